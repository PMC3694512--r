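test_that("builds are named, listed and isolated per committer", {
  srv <- tiny_server()
  cb <- srv$builders
  expect_equal(cb$create_build("dr_who", "12344321"), "default")
  expect_equal(cb$create_build("dr_who", "12344321", description = "ward round"),
               "ward-round")
  expect_setequal(cb$list_builds("dr_who", "12344321"), c("default", "ward-round"))
  expect_equal(cb$list_builds("dr_who"), "12344321")
  expect_length(cb$list_builds("dr_jones", "12344321"), 0L)
  expect_error(cb$create_build("dr_who", "no-such-ehr"), class = "ehrest_not_found")
})

test_that("update-version commits as an amendment, copy-version as a new object", {
  srv <- tiny_server(); st <- srv$store; cb <- srv$builders
  c1 <- commit_bp(st, "12344321", 120, 80)
  uid <- c1$version_uids[[1]]
  cb$create_build("dr_who", "12344321")
  t1 <- cb$add_version("dr_who", "12344321", "default", "update-version",
                       list(version_uid = format(uid)))
  t2 <- cb$add_version("dr_who", "12344321", "default", "copy-version",
                       list(version_uid = format(uid)))
  ctb <- cb$commit_build("dr_who", "12344321", "default")
  expect_length(ctb$version_uids, 2L)
  trees <- vapply(ctb$version_uids, `[[`, character(1), "version_tree_id")
  oids <- vapply(ctb$version_uids, `[[`, character(1), "object_id")
  expect_true("2" %in% trees)                         # the amendment
  expect_true(any(oids != uid$object_id))             # the unrelated copy
  amended <- st$get_version("12344321", uid$object_id, "latest_version")
  expect_equal(format(amended$preceding_uid), format(uid))
  expect_equal(amended$change_type, "amendment")
})

test_that("from-form parses XML or JSON payloads", {
  srv <- tiny_server(); cb <- srv$builders
  cb$create_build("dr_who", "12344321")
  comp <- make_bp_composition(111, 71)
  t1 <- cb$add_version("dr_who", "12344321", "default", "from-form",
                       list(data = composition_to_xml(comp)))
  t2 <- cb$add_version("dr_who", "12344321", "default", "from-form",
                       list(data = composition_to_json(comp)))
  expect_identical(composition_from_xml(cb$get_data("dr_who", "12344321", "default", t1)), comp)
  expect_identical(composition_from_xml(cb$get_data("dr_who", "12344321", "default", t2)), comp)
  expect_error(cb$add_version("dr_who", "12344321", "default", "no-such-command", list()),
               class = "ehrest_bad_request")
})

test_that("from-url sends the fixed restricted Referer and respects the allow list", {
  srv <- tiny_server()
  seen <- new.env()
  recorder <- function(url, headers = list()) {
    seen$url <- url; seen$headers <- headers
    composition_to_xml(make_bp_composition(133, 82))
  }
  cb <- builder_space(srv$store, fetcher = recorder,
                      host = "ehr.example.org", allowed_hosts = "ehr.example.org")
  cb$create_build("dr_who", "12344321")
  cb$add_version("dr_who", "12344321", "default", "from-url",
                 list(url = "http://ehr.example.org/static/bp-example.xml"))
  expect_match(seen$headers$Referer, "/static/restricted.txt$")
  expect_identical(seen$headers$Referer, "ehr.example.org/static/restricted.txt")
  expect_error(
    cb$add_version("dr_who", "12344321", "default", "from-url",
                   list(url = "http://evil.example.com/x")),
    class = "ehrest_bad_request")
})

test_that("from-instance-template substitutes every POSTed variable", {
  srv <- tiny_server()
  template <- composition_to_xml(make_bp_composition(1, 2))
  template <- sub("magnitude=\"1\"", "magnitude=\"{{sys}}\"", template, fixed = TRUE)
  template <- sub("magnitude=\"2\"", "magnitude=\"{{dia}}\"", template, fixed = TRUE)
  cb <- builder_space(srv$store, fetcher = function(url, headers) template,
                      host = "ehr.example.org")
  cb$create_build("dr_who", "12344321")
  tid <- cb$add_version("dr_who", "12344321", "default", "from-instance-template",
                        list(url = "http://ehr.example.org/t.xml", sys = "151", dia = "93"))
  got <- composition_from_xml(cb$get_data("dr_who", "12344321", "default", tid))
  expect_equal(resolve_path_values(got, bp_systolic_path())[[1]], 151)
  expect_equal(resolve_path_values(got, bp_diastolic_path())[[1]], 93)
  expect_error(
    cb$add_version("dr_who", "12344321", "default", "from-instance-template",
                   list(url = "http://ehr.example.org/t.xml", sys = "151")),
    class = "ehrest_bad_request")  # {{dia}} left unbound
})

test_that("from-ehr-path replaces exactly the addressed leaves (tree-diff oracle)", {
  srv <- tiny_server()
  skeleton <- make_bp_composition(0, 0)
  cb <- builder_space(srv$store,
                      fetcher = function(url, headers) composition_to_xml(skeleton),
                      host = "ehr.example.org")
  cb$create_build("dr_who", "12344321")
  sys_leaf <- sub("/magnitude$", "", bp_systolic_path())
  fields <- list(url = "http://ehr.example.org/skel.xml")
  fields[[sys_leaf]] <- "142"
  tid <- cb$add_version("dr_who", "12344321", "default", "from-ehr-path", fields)
  got <- composition_from_xml(cb$get_data("dr_who", "12344321", "default", tid))
  expect_equal(resolve_path_values(got, bp_systolic_path())[[1]], 142)
  # everything off the replaced path is identical to the skeleton
  reset <- replace_at <- got
  expect_identical(resolve_path_values(got, bp_diastolic_path()),
                   resolve_path_values(skeleton, bp_diastolic_path()))
  got_json <- composition_to_json(got)
  skel_json <- composition_to_json(skeleton)
  expect_identical(gsub("142", "0", got_json, fixed = TRUE), skel_json)
  # an unresolvable path errors, naming the offenders
  bad <- list(url = "http://ehr.example.org/skel.xml", `/no/such/path` = "1")
  err <- tryCatch(cb$add_version("dr_who", "12344321", "default", "from-ehr-path", bad),
                  error = function(e) conditionMessage(e))
  expect_match(err, "/no/such/path", fixed = TRUE)
})

test_that("data PUT/GET round-trips; malformed PUT leaves data intact; DELETE removes", {
  srv <- tiny_server(); cb <- srv$builders
  cb$create_build("dr_who", "12344321")
  comp <- make_bp_composition(118, 76)
  tid <- cb$add_version("dr_who", "12344321", "default", "from-form",
                        list(data = composition_to_xml(comp)))
  replacement <- make_bp_composition(140, 90)
  cb$put_data("dr_who", "12344321", "default", tid, composition_to_xml(replacement))
  xml1 <- cb$get_data("dr_who", "12344321", "default", tid, media = "xml")
  expect_identical(composition_from_xml(xml1), replacement)
  expect_error(cb$put_data("dr_who", "12344321", "default", tid, "<broken"),
               class = "ehrest_parse_error")
  expect_identical(cb$get_data("dr_who", "12344321", "default", tid, media = "xml"), xml1)
  html <- cb$get_data("dr_who", "12344321", "default", tid, media = "html")
  expect_match(html, "<form", fixed = TRUE)
  cb$delete_version("dr_who", "12344321", "default", tid)
  b <- cb$get_build("dr_who", "12344321", "default")
  expect_length(b$temp_versions, 0L)
})

test_that("validation reports flag exactly the offending temp version", {
  srv <- tiny_server(); cb <- srv$builders
  cb$create_build("dr_who", "12344321")
  rep0 <- cb$validate_build("dr_who", "12344321", "default")
  expect_equal(rep0$overall, "valid")
  expect_length(rep0$by_temp_id, 0L)
  good <- cb$add_version("dr_who", "12344321", "default", "from-form",
                         list(data = composition_to_xml(make_bp_composition(120, 80))))
  bad_comp <- make_bp_composition(2000, 80)  # outside even the archetype range
  bad <- cb$add_version("dr_who", "12344321", "default", "from-form",
                        list(data = composition_to_xml(bad_comp)))
  rep <- cb$validate_build("dr_who", "12344321", "default")
  expect_equal(rep$overall, "invalid")
  expect_true(is_valid(rep$by_temp_id[[good]]))
  expect_false(is_valid(rep$by_temp_id[[bad]]))
  # the archetype list later forwarded to triggers is present
  expect_true("openEHR-EHR-OBSERVATION.blood_pressure.v1" %in% rep$archetype_ids)
})

test_that("commit destroys the build on success and retains it untouched on failure", {
  srv <- tiny_server(); st <- srv$store; cb <- srv$builders
  cb$create_build("dr_who", "12344321")
  cb$add_version("dr_who", "12344321", "default", "from-form",
                 list(data = composition_to_xml(make_bp_composition(125, 82))))
  ctb <- cb$commit_build("dr_who", "12344321", "default")
  expect_s3_class(ctb, "contribution")
  expect_error(cb$get_build("dr_who", "12344321", "default"), class = "ehrest_not_found")
  # committed content immediately visible at the published URIs
  uid <- format(ctb$version_uids[[1]])
  expect_equal(srv$dispatch("GET", paste0("/ehr:12344321/", uid))$status, 200L)

  cb$create_build("dr_who", "12344321")
  cb$add_version("dr_who", "12344321", "default", "from-form",
                 list(data = composition_to_xml(make_bp_composition(2000, 80))))
  before <- st$serialize_state()
  expect_error(cb$commit_build("dr_who", "12344321", "default"),
               class = "ehrest_validation_error")
  expect_identical(st$serialize_state(), before)
  expect_length(cb$get_build("dr_who", "12344321", "default")$temp_versions, 1L)
})

test_that("uncommitted builds never leak into queries or version lookups", {
  srv <- tiny_server(); st <- srv$store; cb <- srv$builders
  commit_bp(st, "12344321", 200, 100)
  cb$create_build("dr_who", "12344321")
  cb$add_version("dr_who", "12344321", "default", "from-form",
                 list(data = composition_to_xml(make_bp_composition(250, 120))))
  rs <- execute_plan(translate_aql(parse_aql(bp_aql(150, "multi"))), st)
  expect_length(rs$rows, 1L)
  expect_equal(rs$rows[[1]]$systolic, 200)
  expect_length(st$object_ids("12344321"), 1L)
})

test_that("exactly one contribution and one trigger event per commit, any size", {
  srv <- tiny_server(); cb <- srv$builders
  events <- new.env(); events$n <- 0L
  srv$bus$subscribe("/contributions/*", function(msg) events$n <- events$n + 1L)
  cb$create_build("dr_who", "12344321")
  for (i in 1:4) {
    cb$add_version("dr_who", "12344321", "default", "from-form",
                   list(data = composition_to_xml(make_bp_composition(110 + i, 70))))
  }
  n_before <- length(srv$store$list_contributions("12344321", 1, 100))
  cb$commit_build("dr_who", "12344321", "default")
  expect_equal(events$n, 1L)
  expect_equal(length(srv$store$list_contributions("12344321", 1, 100)), n_before + 1L)
})

test_that("the builder's HTTP commands work end to end over dispatch", {
  srv <- tiny_server(); st <- srv$store
  c1 <- commit_bp(st, "12344321", 120, 80)
  uid <- format(c1$version_uids[[1]])
  r1 <- srv$dispatch("POST", "/cb/dr_who/12344321/new-cb-id/")
  expect_equal(r1$status, 303L)
  expect_equal(r1$headers[["Location"]], "/cb/dr_who/12344321/default/")
  r2 <- srv$dispatch("POST", "/cb/dr_who/12344321/default/new/update-version/",
                     headers = list(`Content-Type` = "application/json"),
                     body = jsonlite::toJSON(list(version_uid = uid), auto_unbox = TRUE))
  expect_equal(r2$status, 201L)
  tid <- r2$body
  rh <- srv$dispatch("GET", sprintf("/cb/dr_who/12344321/default/%s/data/", tid),
                     headers = list(Accept = "text/html"))
  expect_equal(rh$status, 200L)
  expect_match(rh$headers[["Content-Type"]], "html")
  rv <- srv$dispatch("GET", "/cb/dr_who/12344321/default/validate/")
  expect_equal(jsonlite::fromJSON(rv$body)$overall, "valid")
  rc <- srv$dispatch("POST", "/cb/dr_who/12344321/default/commit/")
  expect_equal(rc$status, 201L)
  expect_match(rc$headers[["Location"]], "^/ehr:12344321/contributions/")
  expect_equal(srv$dispatch("GET", "/cb/dr_who/12344321/default/")$status, 404L)
})
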