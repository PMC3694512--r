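bp_section_path <- "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]/data/"

test_that("version resources are fetched by full uid, with fragments ignored", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321", 120, 80)
  uid <- format(c1$version_uids[[1]])
  r <- srv$dispatch("GET", sprintf("/ehr:12344321/%s", uid))
  expect_equal(r$status, 200L)
  expect_match(r$headers[["Content-Type"]], "xml")
  doc <- xml2::read_xml(r$body)
  expect_equal(xml2::xml_attr(doc, "uid"), uid)
  # a fragment is client-side: same effect as without it
  r2 <- srv$dispatch("GET", sprintf("/ehr:12344321/%s#somepath", uid))
  expect_equal(r2$status, 200L)
  expect_identical(r2$body, r$body)
})

test_that("a sub-path after the version uid returns only that subtree", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321", 142.5, 88)
  uid <- format(c1$version_uids[[1]])
  r <- srv$dispatch("GET", sprintf("/ehr:12344321/%s%s", uid, bp_section_path))
  expect_equal(r$status, 200L)
  doc <- xml2::read_xml(r$body)
  kids <- xml2::xml_children(doc)
  expect_equal(xml2::xml_name(kids[[1]]), "data")
  expect_match(r$body, "142.5", fixed = TRUE)
  expect_false(grepl("context", r$body))  # siblings outside the sub-path are absent
  r404 <- srv$dispatch("GET", sprintf("/ehr:12344321/%s/absent/path", uid))
  expect_equal(r404$status, 404L)
})

test_that("lookup commands, object commands and contribution routes work", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321", 120, 80, "2005-08-01T10:00:00")
  oid <- c1$version_uids[[1]]$object_id
  amend_bp(st, "12344321", oid, 150, 90, "2005-08-03T10:00:00")
  r <- srv$dispatch("GET", sprintf("/ehr:12344321/%s@latest_version", oid))
  expect_equal(r$status, 200L)
  expect_match(xml2::xml_attr(xml2::read_xml(r$body), "uid"), "::2$")
  r2 <- srv$dispatch("GET", sprintf("/ehr:12344321/%s@2005-08-02T04:30:00", oid))
  expect_match(xml2::xml_attr(xml2::read_xml(r2$body), "uid"), "::1$")
  r3 <- srv$dispatch("GET", sprintf("/ehr:12344321/%s/all_version_ids", oid))
  expect_equal(r3$status, 200L)
  expect_length(jsonlite::fromJSON(r3$body), 2L)
  r4 <- srv$dispatch("GET", "/ehr:12344321/contributions/?start=1&end=1&descending=true")
  expect_equal(r4$status, 200L)
  expect_equal(xml2::xml_length(xml2::read_xml(r4$body)), 1L)
  cid <- st$list_contributions("12344321")[[1]]$id
  r5 <- srv$dispatch("GET", sprintf("/ehr:12344321/contributions/%s/", cid))
  expect_equal(r5$status, 200L)
  expect_equal(jsonlite::fromJSON(r5$body)$id, cid)
})

test_that("unknown routes give 404 and wrong methods 405; OPTIONS answers Allow", {
  srv <- tiny_server()
  expect_equal(srv$dispatch("GET", "/nonexistent")$status, 404L)
  expect_equal(srv$dispatch("DELETE", "/ehr:12344321/contributions/")$status, 405L)
  expect_equal(srv$dispatch("PUT", "/static/restricted.txt")$status, 405L)
  o <- srv$dispatch("OPTIONS", "/ehr:12344321/contributions/")
  expect_equal(o$status, 200L)
  expect_match(o$headers[["Allow"]], "GET")
})

test_that("media negotiation defaults to XML and honours Accept", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321")
  uid <- format(c1$version_uids[[1]])
  expect_match(srv$dispatch("GET", paste0("/ehr:12344321/", uid))$headers[["Content-Type"]], "xml")
  rj <- srv$dispatch("GET", paste0("/ehr:12344321/", uid),
                     headers = list(Accept = "application/json"))
  expect_match(rj$headers[["Content-Type"]], "json")
  expect_equal(jsonlite::fromJSON(rj$body)$uid, uid)
  r406 <- srv$dispatch("GET", paste0("/ehr:12344321/", uid),
                       headers = list(Accept = "image/png"))
  expect_equal(r406$status, 406L)
  expect_identical(negotiate_media(NULL), "application/xml")
  expect_identical(negotiate_media("application/json, application/xml"), "application/json")
  expect_identical(negotiate_media("*/*"), "application/xml")
})

test_that("cache headers follow the three resource classes", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321")
  uid <- format(c1$version_uids[[1]])
  rv <- srv$dispatch("GET", paste0("/ehr:12344321/", uid))
  expect_match(rv$headers[["Cache-Control"]], "^private, max-age=")
  expect_false("ETag" %in% names(rv$headers))   # immutable: update checking is irrelevant
  rs <- srv$dispatch("GET", "/static/restricted.txt")
  expect_match(rs$headers[["Cache-Control"]], "^public, max-age=")
  rm_ <- srv$dispatch("GET", sprintf("/ehr:12344321/%s@latest_version", c1$version_uids[[1]]$object_id))
  expect_equal(rm_$headers[["ETag"]], paste0("\"", c1$id, "\""))
  expect_match(rm_$headers[["Last-Modified"]], "GMT$")
})

test_that("the record ETag changes iff a new contribution is committed", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321")
  oid <- c1$version_uids[[1]]$object_id
  etag_of <- function() {
    srv$dispatch("GET", sprintf("/ehr:12344321/%s@latest_version", oid))$headers[["ETag"]]
  }
  e1 <- etag_of(); e2 <- etag_of()
  expect_identical(e1, e2)                       # reads do not move the validator
  # any contribution to the record -- even an administrative access-rules
  # object, versioned like everything else -- moves the ETag
  access_doc <- rm_node("ehr_access", children = list(
    rm_node("policy", value = leaf_text("team-only"))))
  st$commit_contribution("12344321",
    list(list(change_type = "creation", data = access_doc)),
    audit = list(committer_id = "admin", description = "access change"),
    commit_time = parse_ehr_time("2005-09-01T00:00:00"))
  expect_false(identical(etag_of(), e1))
})

test_that("a matching If-None-Match answers 304 with zero store reads", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321")
  oid <- c1$version_uids[[1]]$object_id
  etag <- paste0("\"", c1$id, "\"")
  reads <- st$read_count()
  r <- srv$dispatch("GET", sprintf("/ehr:12344321/%s@latest_version", oid),
                    headers = list(`If-None-Match` = etag))
  expect_equal(r$status, 304L)
  expect_equal(st$read_count(), reads)
  # non-matching validator serves normally
  r2 <- srv$dispatch("GET", sprintf("/ehr:12344321/%s@latest_version", oid),
                     headers = list(`If-None-Match` = "\"other\""))
  expect_equal(r2$status, 200L)
  expect_gt(st$read_count(), reads)
})

test_that("a stale If-Match on a conditional write gives 412 and changes nothing", {
  srv <- tiny_server(); st <- srv$store
  commit_bp(st, "12344321")
  before <- st$serialize_state()
  body <- jsonlite::toJSON(list(versions = list(list(
    change_type = "creation", data = node_to_list(make_bp_composition(110, 70))))),
    auto_unbox = TRUE)
  r <- srv$dispatch("POST", "/ehr:12344321/contributions/",
                    headers = list(`If-Match` = "\"stale\"",
                                   `Content-Type` = "application/json"),
                    body = body)
  expect_equal(r$status, 412L)
  expect_identical(st$serialize_state(), before)
  # matching If-Match commits
  etag <- paste0("\"", st$metadata("12344321")$last_contribution_id, "\"")
  r2 <- srv$dispatch("POST", "/ehr:12344321/contributions/",
                     headers = list(`If-Match` = etag, `Content-Type` = "application/json"),
                     body = body)
  expect_equal(r2$status, 201L)
})

test_that("state-creating POSTs answer with Location (and Content-Location for queries)", {
  srv <- tiny_server(); st <- srv$store
  commit_bp(st, "12344321")
  r_ehr <- srv$dispatch("POST", "/ehr/")
  expect_equal(r_ehr$status, 201L)
  expect_match(r_ehr$headers[["Location"]], "^/ehr:")
  r_q <- srv$dispatch("POST", "/ehr:12344321/q/AQL/",
                      headers = list(`Content-Type` = "application/json"),
                      body = jsonlite::toJSON(list(q = bp_aql(185, "single"),
                                                   `_from` = "2005-01-01"), auto_unbox = TRUE))
  expect_equal(r_q$status, 303L)
  expect_match(r_q$headers[["Location"]], "^/ehr:12344321/q/AQL/[0-9a-f]{40}/\\?from=2005-01-01$")
  expect_match(r_q$headers[["Content-Location"]], "^/ehr:12344321/q/AQL/[0-9a-f]{40}/$")
  r_body <- jsonlite::toJSON(list(versions = list(list(
    change_type = "creation", data = node_to_list(make_bp_composition(110, 70))))),
    auto_unbox = TRUE)
  r_c <- srv$dispatch("POST", "/ehr:12344321/contributions/",
                      headers = list(`Content-Type` = "application/json"), body = r_body)
  expect_equal(r_c$status, 201L)
  expect_match(r_c$headers[["Location"]], "^/ehr:12344321/contributions/")
})

test_that("the redirected GET of a stored query is logged with sha and parameters", {
  srv <- tiny_server(); st <- srv$store
  commit_bp(st, "12344321", 190, 95)
  r <- srv$dispatch("POST", "/ehr:12344321/q/AQL/",
                    headers = list(`Content-Type` = "application/json",
                                   `X-Committer` = "dr_who"),
                    body = jsonlite::toJSON(list(q = bp_aql(185, "single")), auto_unbox = TRUE))
  loc <- r$headers[["Location"]]
  r2 <- srv$dispatch("GET", loc, headers = list(`X-Committer` = "dr_who"))
  expect_equal(r2$status, 200L)
  log <- srv$log_lines()
  sha <- sub(".*/([0-9a-f]{40})/.*", "\\1", loc)
  hit <- grep(sprintf("GET .*%s", sha), log, value = TRUE)
  expect_gte(length(hit), 1L)
  expect_match(hit[length(hit)], "dr_who")
  expect_match(log[length(log) - 1L], "^\\S+ - \\S+ \\[[^]]+\\] \"")  # NCSA-shaped
})

test_that("query info and debug are served over the URI grammar", {
  srv <- tiny_server(); st <- srv$store
  commit_bp(st, "12344321", 190, 95)
  r <- srv$dispatch("POST", "/ehr:12344321/q/AQL/",
                    body = list(q = bp_aql(185, "single"), cfg = "7"))
  base <- r$headers[["Content-Location"]]
  info <- srv$dispatch("GET", paste0(base, "info/"), headers = list(Accept = "application/json"))
  expect_equal(info$status, 200L)
  parsed <- jsonlite::fromJSON(info$body)
  expect_identical(parsed$text, bp_aql(185, "single"))
  expect_identical(parsed$static_params$cfg, "7")
  reads <- st$read_count()
  dbg <- srv$dispatch("GET", paste0(base, "?debug=true"))
  expect_equal(dbg$status, 200L)
  expect_match(dbg$body, "NATIVE QUERY PLAN", fixed = TRUE)
  expect_equal(st$read_count(), reads)
})

test_that("GET and OPTIONS traffic never mutates store state", {
  srv <- generate_population(population_spec(n_patients = 3, seed = 41))
  st <- srv$store
  eid <- st$ehr_ids()[1]
  oid <- st$object_ids(eid)[1]
  uid <- format(st$get_version(eid, oid, "latest_version")$uid)
  before <- st$serialize_state()
  uris <- c("/", "/static/restricted.txt", sprintf("/ehr:%s/contributions/", eid),
            sprintf("/ehr:%s/%s@latest_version", eid, oid),
            sprintf("/ehr:%s/%s", eid, uid),
            sprintf("/ehr:%s/%s/all_version_ids", eid, oid),
            "/cb/", "/cb/dr_who/", "/nonexistent", "/bm/zzzzzz",
            sprintf("/multi/ehr:%s/%s@latest_version", eid, oid))
  set.seed(5)
  for (u in sample(rep(uris, 3))) {
    srv$dispatch("GET", u)
    srv$dispatch("OPTIONS", u)
  }
  expect_identical(st$serialize_state(), before)
})

test_that("multi-prefixed reads are served from the configured replica", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321", 120, 80, "2005-08-01T10:00:00")
  oid <- c1$version_uids[[1]]$object_id
  replica <- replicate_to_multi(st, lag = 0)
  srv$set_replica(replica)
  # a commit after the replica cut-off is visible on the live path only
  amend_bp(st, "12344321", oid, 180, 95, "2005-08-02T10:00:00")
  live <- srv$dispatch("GET", sprintf("/ehr:12344321/%s@latest_version", oid))
  lagged <- srv$dispatch("GET", sprintf("/multi/ehr:12344321/%s@latest_version", oid))
  expect_match(xml2::xml_attr(xml2::read_xml(live$body), "uid"), "::2$")
  expect_match(xml2::xml_attr(xml2::read_xml(lagged$body), "uid"), "::1$")
})
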