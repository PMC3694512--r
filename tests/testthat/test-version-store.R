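test_that("record creation enforces uniqueness and id validity", {
  st <- version_store()
  st$create_ehr("12344321")
  expect_error(st$create_ehr("12344321"), class = "ehrest_conflict")
  expect_error(st$create_ehr("bad/id"), class = "ehrest_bad_request")
  a <- st$create_ehr(); b <- st$create_ehr()
  expect_false(identical(a, b))
})

test_that("auto-generated record ids are pairwise distinct at scale", {
  st <- version_store()
  set.seed(7)
  ids <- vapply(1:10000, function(i) st$create_ehr(), character(1))
  expect_equal(length(unique(ids)), 10000L)
})

test_that("commit mints trunk tree ids and links amendments", {
  st <- version_store("test2.eee.mi.imt.liu.se")
  id <- st$create_ehr("12344321")
  c1 <- commit_bp(st, id)
  expect_length(c1$version_uids, 1L)
  u1 <- c1$version_uids[[1]]
  expect_equal(u1$version_tree_id, "1")
  expect_equal(u1$creating_system_id, "test2.eee.mi.imt.liu.se")
  c2 <- amend_bp(st, id, u1$object_id, 150)
  u2 <- c2$version_uids[[1]]
  expect_equal(u2$version_tree_id, "2")
  expect_equal(u2$object_id, u1$object_id)
  v2 <- st$get_version(id, u1$object_id, u2)
  expect_equal(format(v2$preceding_uid), format(u1))
})

test_that("commit is all-or-nothing under a failing spec at every position", {
  good <- function(t) list(change_type = "creation", data = make_bp_composition(120, 80, t))
  bad_specs <- list(
    list(change_type = "creation", data = rm_node("composition", value = leaf_quantity(NaN, "x"))),
    list(change_type = "amendment", preceding_uid = "nope::sys::1",
         data = make_bp_composition(120, 80)),
    list(change_type = "bogus")
  )
  for (bad in bad_specs) {
    for (pos in 1:3) {
      srv <- tiny_server()
      st <- srv$store
      commit_bp(st, "12344321")
      before <- st$serialize_state()
      meta_before <- st$metadata("12344321")
      specs <- list(good("2005-08-02T00:00:00"), good("2005-08-03T00:00:00"),
                    good("2005-08-04T00:00:00"))
      specs[[pos]] <- bad
      expect_error(
        st$commit_contribution("12344321", specs, audit = list(committer_id = "x")),
        class = "ehrest_error")
      expect_identical(st$serialize_state(), before)
      expect_identical(st$metadata("12344321"), meta_before)
    }
  }
})

test_that("stale preceding version is a conflict and stores nothing", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321")
  u1 <- c1$version_uids[[1]]
  amend_bp(st, "12344321", u1$object_id, 150)
  before <- st$serialize_state()
  expect_error(
    st$commit_contribution("12344321",
      list(list(change_type = "amendment", preceding_uid = u1,
                data = make_bp_composition(99, 66))),
      audit = list(committer_id = "x")),
    class = "ehrest_conflict")
  expect_identical(st$serialize_state(), before)
})

test_that("version lookup supports uid, latest and at-time selectors", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321", 120, 80, "2005-08-01T10:00:00")
  oid <- c1$version_uids[[1]]$object_id
  amend_bp(st, "12344321", oid, 150, 90, "2005-08-03T10:00:00")
  amend_bp(st, "12344321", oid, 170, 95, "2005-08-05T10:00:00")

  expect_equal(st$get_version("12344321", oid, "latest_version")$uid$version_tree_id, "3")
  # the version current at the example instant: between commits 1 and 2
  v <- st$get_version("12344321", oid, "2005-08-02T04:30:00")
  expect_equal(v$uid$version_tree_id, "1")
  # replay oracle: rebuild from scratch with only commits <= t and compare
  t <- parse_ehr_time("2005-08-03T12:00:00")
  fresh <- version_store_from_log(
    Filter(function(ln) {
      rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
      tm <- if (identical(rec$event, "create_ehr")) rec$time else rec$commit_time
      parse_ehr_time(tm) <= t
    }, st$serialize_state()))
  expect_equal(format(st$get_version("12344321", oid, t)$uid),
               format(fresh$get_version("12344321", oid, "latest_version")$uid))
  expect_error(st$get_version("12344321", oid, "2004-01-01T00:00:00"),
               class = "ehrest_not_found")
  expect_error(st$get_version("12344321", "unknown", "latest_version"),
               class = "ehrest_not_found")
})

test_that("all_version_ids is in commit order and matches replay", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321")
  oid <- c1$version_uids[[1]]$object_id
  expect_length(st$all_version_ids("12344321", oid), 1L)
  for (k in 2:5) amend_bp(st, "12344321", oid, 100 + k, 80, sprintf("2005-08-%02dT10:00:00", k))
  ids <- vapply(st$all_version_ids("12344321", oid), format, character(1))
  expect_length(ids, 5L)
  replayed <- version_store_from_log(st$serialize_state())
  expect_identical(vapply(replayed$all_version_ids("12344321", oid), format, character(1)), ids)
  expect_error(st$all_version_ids("12344321", "nope"), class = "ehrest_not_found")
})

test_that("contribution paging defaults to the 20 most recent, 1-based", {
  srv <- tiny_server(); st <- srv$store
  for (k in 1:25) commit_bp(st, "12344321", 100 + k, 80, sprintf("2005-03-%02dT10:00:00", k))
  page <- st$list_contributions("12344321")
  expect_length(page, 20L)
  # newest first: first entry is the last committed
  expect_equal(page[[1]]$commit_time, parse_ehr_time("2005-03-25T10:00:00"))
  top5 <- st$list_contributions("12344321", start = 1, end = 5, descending = TRUE)
  expect_length(top5, 5L)
  expect_equal(top5[[1]]$id, page[[1]]$id)
  asc <- st$list_contributions("12344321", start = 1, end = 5, descending = FALSE)
  expect_equal(asc[[1]]$commit_time, parse_ehr_time("2005-03-01T10:00:00"))
  expect_error(st$list_contributions("12344321", start = 0, end = 5), class = "ehrest_bad_request")
  expect_error(st$list_contributions("12344321", start = 6, end = 5), class = "ehrest_bad_request")
  empty <- tiny_server("empty1")$store
  expect_length(empty$list_contributions("empty1"), 0L)
})

test_that("metadata reflects the latest contribution and is served from cache", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321")
  m <- st$metadata("12344321")
  expect_equal(m$last_contribution_id, c1$id)
  expect_equal(m$last_modified, c1$commit_time)
  # warm cache: repeated metadata() performs no further store reads
  reads <- st$read_count()
  st$metadata("12344321"); st$metadata("12344321")
  expect_equal(st$read_count(), reads)
  # cold cache: exactly one read refills it
  st$evict_metadata("12344321")
  st$metadata("12344321"); st$metadata("12344321")
  expect_equal(st$read_count(), reads + 1L)
  expect_error(st$metadata("nope"), class = "ehrest_not_found")
})

test_that("the store is append-only: earlier state is a byte prefix of later state", {
  srv <- tiny_server(); st <- srv$store
  states <- list(st$serialize_state())
  c1 <- commit_bp(st, "12344321")
  states <- c(states, list(st$serialize_state()))
  amend_bp(st, "12344321", c1$version_uids[[1]]$object_id, 150)
  states <- c(states, list(st$serialize_state()))
  delete_bp(st, "12344321", c1$version_uids[[1]]$object_id)
  states <- c(states, list(st$serialize_state()))
  for (i in 1:(length(states) - 1L)) {
    expect_identical(states[[i]], states[[i + 1L]][seq_along(states[[i]])])
  }
})

test_that("logical deletion adds a data-less version and keeps history fetchable", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321")
  oid <- c1$version_uids[[1]]$object_id
  delete_bp(st, "12344321", oid)
  latest <- st$get_version("12344321", oid, "latest_version")
  expect_equal(latest$change_type, "deleted")
  expect_null(latest$data)
  expect_equal(latest$uid$version_tree_id, "2")
  v1 <- st$get_version("12344321", oid, c1$version_uids[[1]])
  expect_false(is.null(v1$data))
  expect_length(st$all_version_ids("12344321", oid), 2L)
})

test_that("snapshot at time t equals replaying only contributions up to t", {
  srv <- generate_population(population_spec(n_patients = 6, seed = 11))
  st <- srv$store
  t <- parse_ehr_time("2005-07-01T00:00:00")
  replayed <- version_store_from_log(
    Filter(function(ln) {
      rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
      tm <- if (identical(rec$event, "create_ehr")) rec$time else rec$commit_time
      parse_ehr_time(tm) <= t
    }, st$serialize_state()))
  for (eid in replayed$ehr_ids()) {
    for (oid in replayed$object_ids(eid)) {
      expect_identical(
        format(st$get_version(eid, oid, t)$uid),
        format(replayed$get_version(eid, oid, "latest_version")$uid))
    }
  }
})

test_that("log replay reproduces the store byte for byte", {
  srv <- generate_population(population_spec(n_patients = 5, seed = 13))
  lines <- srv$store$serialize_state()
  replayed <- version_store_from_log(lines)
  expect_identical(replayed$serialize_state(), lines)
  path <- tempfile(fileext = ".ndjson")
  srv$store$export_log(path)
  from_file <- version_store_from_log(file = path)
  expect_identical(from_file$serialize_state(), lines)
})

test_that("attestation versions reference their target and carry proof", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321")
  u1 <- c1$version_uids[[1]]
  ca <- st$commit_contribution("12344321",
    list(list(change_type = "attestation", preceding_uid = u1,
              attestation_proof = "signed by dr_who")),
    audit = list(committer_id = "dr_who", description = "attested"),
    commit_time = parse_ehr_time("2005-08-02T00:00:00"))
  va <- st$get_version("12344321", u1$object_id, ca$version_uids[[1]])
  expect_equal(va$change_type, "attestation")
  expect_equal(format(va$preceding_uid), format(u1))
  expect_equal(va$attestation_proof, "signed by dr_who")
})
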