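# Shared generators and independent oracles for the test suite.
# Everything here is deliberately naive: recursive brute force, no reuse of
# the implementation's internal matching machinery.

# -- random document trees ----------------------------------------------------

random_leaf <- function() {
  switch(sample(4L, 1L),
    leaf_quantity(round(stats::runif(1, 0, 500), 3), sample(c("mm[Hg]", "kg", "1/min"), 1L)),
    leaf_coded_text(sample(c("at0001", "at0002", "C1"), 1L), "local", "label"),
    leaf_text(paste(sample(letters, 5L), collapse = "")),
    leaf_timestamp("2005-08-02T04:30:00")
  )
}

random_tree <- function(max_nodes = 200L) {
  budget <- sample.int(max_nodes, 1L)
  names_pool <- c("content", "items", "data", "events", "value", "context")
  ids_pool <- list(NULL, "at0001", "at0002", "openEHR-EHR-SECTION.vital_signs.v1")
  build <- function(depth) {
    budget <<- budget - 1L
    nm <- sample(names_pool, 1L)
    nid <- ids_pool[[sample.int(length(ids_pool), 1L)]]
    if (budget <= 0L || depth > 5L || stats::runif(1) < 0.35) {
      if (stats::runif(1) < 0.7) return(rm_node(nm, nid, value = random_leaf()))
      return(rm_node(nm, nid))  # empty container
    }
    n_kids <- sample.int(4L, 1L)
    kids <- list()
    for (i in seq_len(n_kids)) {
      if (budget <= 0L) break
      kids[[length(kids) + 1L]] <- build(depth + 1L)
    }
    rm_node(nm, nid, children = kids)
  }
  build(1L)
}

random_path <- function(max_segments = 4L) {
  n <- sample.int(max_segments, 1L)
  segs <- lapply(seq_len(n), function(i) {
    list(attribute_name = sample(c("content", "items", "data", "events", "value"), 1L),
         predicate = if (stats::runif(1) < 0.4) sample(c("at0001", "at0002"), 1L) else NULL)
  })
  rm_path(segs)
}

# Brute-force path resolution: flatten every root-to-node chain and filter.
brute_resolve <- function(root, path) {
  segs <- path$segments
  hits <- list()
  walk <- function(node, depth) {
    if (depth > length(segs)) return(invisible(NULL))
    seg <- segs[[depth]]
    matches <- identical(node$name, seg$attribute_name) &&
      (is.null(seg$predicate) || identical(node$node_id, seg$predicate))
    if (!matches) return(invisible(NULL))
    if (depth == length(segs)) {
      hits[[length(hits) + 1L]] <<- node
    } else {
      for (ch in node$children) walk(ch, depth + 1L)
    }
    invisible(NULL)
  }
  if (length(segs) == 0L) return(list(root))
  for (ch in root$children) walk(ch, 1L)
  hits
}

random_version_uid <- function() {
  tok <- function(n) paste(sample(c(letters, 0:9), n, replace = TRUE), collapse = "")
  version_uid(
    paste(tok(8), tok(4), sep = "-"),
    paste(tok(5), "example.org", sep = "."),
    paste(sample.int(9L, sample.int(3L, 1L), replace = TRUE), collapse = ".")
  )
}

# -- populated servers ---------------------------------------------------------

tiny_server <- function(ehr_id = "12344321") {
  srv <- ehr_server()
  srv$store$create_ehr(ehr_id, time = parse_ehr_time("2005-01-01T00:00:00"))
  srv
}

commit_bp <- function(store, ehr_id, systolic = 120, diastolic = 80,
                      when = "2005-08-01T10:00:00", committer = "dr_who") {
  store$commit_contribution(
    ehr_id,
    list(list(change_type = "creation",
              data = make_bp_composition(systolic, diastolic, when))),
    audit = list(committer_id = committer, description = "bp recording"),
    commit_time = parse_ehr_time(when))
}

amend_bp <- function(store, ehr_id, object_id, systolic, diastolic = 80,
                     when = "2005-08-05T10:00:00") {
  latest <- store$get_version(ehr_id, object_id, "latest_version")
  store$commit_contribution(
    ehr_id,
    list(list(change_type = "amendment", preceding_uid = latest$uid,
              data = make_bp_composition(systolic, diastolic, when))),
    audit = list(committer_id = "dr_who", description = "amendment"),
    commit_time = parse_ehr_time(when))
}

delete_bp <- function(store, ehr_id, object_id, when = "2005-08-09T10:00:00") {
  latest <- store$get_version(ehr_id, object_id, "latest_version")
  store$commit_contribution(
    ehr_id,
    list(list(change_type = "deleted", preceding_uid = latest$uid)),
    audit = list(committer_id = "dr_who", description = "logical deletion"),
    commit_time = parse_ehr_time(when))
}

# Oracle wrapper for the canonical blood-pressure query at a threshold, with
# an independently constructed predicate (no AST involved).
bp_oracle <- function(store, threshold, op = `>`) {
  oracle_query(
    store,
    containments = c("openEHR-EHR-COMPOSITION.encounter.v1",
                     "openEHR-EHR-OBSERVATION.blood_pressure.v1"),
    select = list(systolic = bp_systolic_path("observation"),
                  diastolic = bp_diastolic_path("observation")),
    predicate = function(chain) {
      vals <- resolve_path_values(chain[[length(chain)]], bp_systolic_path("observation"))
      length(vals) > 0L && op(vals[[1]], threshold)
    })
}
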