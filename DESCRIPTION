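Package: ehrest
Title: RESTful Versioned Storage, Querying and Messaging for Archetype-Based Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, self-contained implementation of a REST-style service
    architecture for archetype-based (openEHR-flavoured) electronic health
    records. Provides append-only versioned storage with atomic contribution
    commits, path addressing over clinical document trees, an AQL-subset query
    engine behind a content-addressed store-and-redirect query protocol, HTTP
    cache-header computation keyed on per-record change state, a per-user
    contribution-builder editing workspace, three-level instance validation
    with constraint-driven skeleton generation, opaque bookmark redirection
    with change detection, commit-event trigger messaging over text frames,
    and a deterministic synthetic-population generator for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    R6,
    digest,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    openssl,
    httpuv
Config/testthat/edition: 3
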