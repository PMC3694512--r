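#' @title Deterministic synthetic EHR populations
#'
#' @description
#' Every component is testable without external data: this module generates
#' multi-patient populations of timestamped contributions containing
#' blood-pressure observations, with configurable amendment and logical-
#' deletion rates, plus the brute-force query oracle the AQL engine is tested
#' against and a lagged replica builder for the multi-record (population)
#' read path. Generation is deterministic per seed: each patient draws from a
#' stream seeded by (population seed, patient counter), so adding patients
#' never perturbs earlier patients' data.
#'
#' @name synthetic_fixtures
NULL

#' Canonical blood-pressure paths and query
#'
#' The shipped composition dialect places the systolic and diastolic
#' magnitudes at fixed paths under the vital-signs section; these helpers
#' return those paths (composition-rooted, or observation-rooted for use
#' after a CONTAINS alias) and the canonical threshold query ("all blood
#' pressures with a systolic value above the threshold").
#'
#' @param from `"composition"` or `"observation"` root.
#' @return A path string.
#' @export
bp_systolic_path <- function(from = c("composition", "observation")) {
  from <- match.arg(from)
  obs <- "/data[at0001]/events[at0006]/data[at0003]/items[at0004]/value/magnitude"
  if (from == "observation") obs
  else paste0("/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]", obs)
}

#' @rdname bp_systolic_path
#' @export
bp_diastolic_path <- function(from = c("composition", "observation")) {
  from <- match.arg(from)
  obs <- "/data[at0001]/events[at0006]/data[at0003]/items[at0005]/value/magnitude"
  if (from == "observation") obs
  else paste0("/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]", obs)
}

#' @rdname bp_systolic_path
#' @param threshold Systolic cut-off in mm[Hg] (default 185).
#' @param scope `"single"` (binds `$current_ehr_uid`) or `"multi"`.
#' @return `bp_aql()`: AQL query text.
#' @export
bp_aql <- function(threshold = 185, scope = c("single", "multi")) {
  scope <- match.arg(scope)
  ehr_pred <- if (scope == "single") " [ehr_id=$current_ehr_uid]" else ""
  paste0(
    "SELECT o", bp_systolic_path("observation"), " AS systolic,\n",
    "       o", bp_diastolic_path("observation"), " AS diastolic\n",
    "FROM EHR e", ehr_pred, "\n",
    "CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter.v1]\n",
    "CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]\n",
    "WHERE o", bp_systolic_path("observation"), " > ", format_num(threshold))
}

#' Build a blood-pressure composition
#'
#' @param systolic,diastolic Magnitudes in mm[Hg].
#' @param time ISO 8601 event time.
#' @return An `rm_node` conforming to the shipped constraint documents.
#' @export
make_bp_composition <- function(systolic, diastolic, time = "2005-08-02T04:30:00") {
  rm_node("composition", "openEHR-EHR-COMPOSITION.encounter.v1", children = list(
    rm_node("context", children = list(
      rm_node("start_time", value = leaf_timestamp(time))
    )),
    rm_node("content", "openEHR-EHR-SECTION.vital_signs.v1", children = list(
      rm_node("items", "openEHR-EHR-OBSERVATION.blood_pressure.v1", children = list(
        rm_node("data", "at0001", children = list(
          rm_node("events", "at0006", children = list(
            rm_node("time", value = leaf_timestamp(time)),
            rm_node("data", "at0003", children = list(
              rm_node("items", "at0004", children = list(
                rm_node("value", value = leaf_quantity(systolic, "mm[Hg]"))
              )),
              rm_node("items", "at0005", children = list(
                rm_node("value", value = leaf_quantity(diastolic, "mm[Hg]"))
              ))
            ))
          ))
        ))
      ))
    ))
  ))
}

#' Specify a synthetic population
#'
#' Defaults describe a small vital-signs cohort: systolic pressures
#' Normal(130, 20) clipped to [60, 260] mm[Hg], diastolic Normal(80, 10)
#' clipped to [30, 160], 1--5 contributions per patient over calendar year
#' 2005, amendments at rate 0.2 and logical deletions at rate 0.05. Clipping
#' keeps every generated value inside the shipped template ranges.
#'
#' @param n_patients Number of records.
#' @param contributions_per_patient `c(min, max)` contributions each.
#' @param seed Integer population seed.
#' @param systolic,diastolic `c(mean, sd)` of the vitals model.
#' @param amendment_rate,deletion_rate Per-contribution probabilities of
#'   amending / logically deleting an existing observation instead of
#'   creating a new one.
#' @param span `c(start, end)` ISO timestamps bounding commit times.
#' @return A `population_spec`.
#' @export
population_spec <- function(n_patients = 20L,
                            contributions_per_patient = c(1L, 5L),
                            seed = 1L,
                            systolic = c(mean = 130, sd = 20),
                            diastolic = c(mean = 80, sd = 10),
                            amendment_rate = 0.2,
                            deletion_rate = 0.05,
                            span = c("2005-01-01T00:00:00", "2005-12-31T23:59:59")) {
  stopifnot(n_patients >= 0L,
            length(contributions_per_patient) == 2L,
            contributions_per_patient[1] >= 1L,
            contributions_per_patient[2] >= contributions_per_patient[1],
            amendment_rate >= 0, amendment_rate <= 1,
            deletion_rate >= 0, deletion_rate <= 1,
            amendment_rate + deletion_rate <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 contributions_per_patient = as.integer(contributions_per_patient),
                 seed = as.integer(seed), systolic = systolic, diastolic = diastolic,
                 amendment_rate = amendment_rate, deletion_rate = deletion_rate,
                 span = span),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %d patient(s), %d-%d contributions each, seed %d\n",
              x$n_patients, x$contributions_per_patient[1], x$contributions_per_patient[2], x$seed))
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

patient_seed <- function(seed, k) {
  # keep derived seeds well inside 32-bit integer range
  as.integer((as.numeric(seed) * 100003 + 7919 * as.numeric(k)) %% 2147483563) + 1L
}

#' Generate a synthetic population into a server
#'
#' Per patient: a record, then a stream of contributions at strictly
#' increasing times -- blood-pressure creations, amendments of existing
#' observations, and logical deletions at the configured rates. All
#' compositions conform to the shipped constraint documents by construction.
#' Identical spec + seed yields a byte-identical commit log.
#'
#' @param spec A [population_spec()].
#' @param server An `EhrServer` to populate; a fresh one is created when
#'   `NULL`.
#' @return The populated `EhrServer` (its `$store` is the populated store).
#' @export
generate_population <- function(spec, server = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  server <- server %||% ehr_server()
  store <- server$store
  t0 <- as.numeric(parse_ehr_time(spec$span[1]))
  t1 <- as.numeric(parse_ehr_time(spec$span[2]))
  for (k in seq_len(spec$n_patients)) {
    set.seed(patient_seed(spec$seed, k))
    n <- spec$contributions_per_patient[1] +
      sample.int(spec$contributions_per_patient[2] - spec$contributions_per_patient[1] + 1L, 1L) - 1L
    times <- sort(round(stats::runif(n + 1L, t0, t1)))
    ehr_id <- store$create_ehr(time = as.POSIXct(times[1], origin = "1970-01-01", tz = "UTC"))
    live <- character(0)      # object ids whose latest version is not deleted
    for (j in seq_len(n)) {
      when <- as.POSIXct(times[j + 1L], origin = "1970-01-01", tz = "UTC")
      sys_bp <- round(clip(stats::rnorm(1, spec$systolic[["mean"]], spec$systolic[["sd"]]), 60, 260), 1)
      dia_bp <- round(clip(stats::rnorm(1, spec$diastolic[["mean"]], spec$diastolic[["sd"]]), 30, 160), 1)
      u <- stats::runif(1)
      if (u < spec$deletion_rate && length(live) > 0L) {
        oid <- live[sample.int(length(live), 1L)]
        latest <- store$get_version(ehr_id, oid, "latest_version")
        store$commit_contribution(ehr_id, list(list(
          change_type = "deleted", preceding_uid = latest$uid)),
          audit = list(committer_id = "generator", description = "logical deletion"),
          commit_time = when)
        live <- setdiff(live, oid)
      } else if (u < spec$deletion_rate + spec$amendment_rate && length(live) > 0L) {
        oid <- live[sample.int(length(live), 1L)]
        latest <- store$get_version(ehr_id, oid, "latest_version")
        store$commit_contribution(ehr_id, list(list(
          change_type = "amendment", preceding_uid = latest$uid,
          data = make_bp_composition(sys_bp, dia_bp, format_ehr_time(when)))),
          audit = list(committer_id = "generator", description = "amended blood pressure"),
          commit_time = when)
      } else {
        ctb <- store$commit_contribution(ehr_id, list(list(
          change_type = "creation",
          data = make_bp_composition(sys_bp, dia_bp, format_ehr_time(when)))),
          audit = list(committer_id = "generator", description = "blood pressure recording"),
          commit_time = when)
        live <- c(live, ctb$version_uids[[1]]$object_id)
      }
    }
  }
  server
}

#' Brute-force query oracle
#'
#' Exhaustively scans every latest, non-deleted composition with
#' [resolve_path()] -- fully independent of the AQL engine's compiled plan
#' machinery -- applying a containment-archetype chain, a predicate over the
#' bound nodes, and select paths. Used as the reference the engine must
#' reproduce.
#'
#' @param store A `VersionStore`.
#' @param containments Character vector of archetype ids: the first must match
#'   the composition root, later ones bind descendant subtrees.
#' @param select Named list of paths (strings) relative to the innermost
#'   containment binding.
#' @param predicate `function(bound_nodes) -> logical`, where `bound_nodes` is
#'   the list of nodes bound by the containment chain (innermost last);
#'   `NULL` accepts everything.
#' @return A `result_set`.
#' @export
oracle_query <- function(store, containments, select, predicate = NULL) {
  columns <- names(select)
  rows <- list(); prov <- character(0)
  walk_archetype <- function(node, id) {
    out <- list()
    rec <- function(nd) {
      if (identical(nd$node_id, id)) out[[length(out) + 1L]] <<- nd
      for (ch in nd$children) rec(ch)
    }
    for (ch in node$children) rec(ch)
    out
  }
  for (eid in sort(store$ehr_ids())) {
    for (v in store$latest_versions(eid)) {
      if (identical(v$change_type, "deleted") || is.null(v$data)) next
      if (length(containments) >= 1L && !identical(v$data$node_id, containments[1])) next
      frontier <- list(list(v$data))
      for (id in containments[-1]) {
        nxt <- list()
        for (chain in frontier) {
          inner <- chain[[length(chain)]]
          for (hit in walk_archetype(inner, id)) nxt[[length(nxt) + 1L]] <- c(chain, list(hit))
        }
        frontier <- nxt
      }
      for (chain in frontier) {
        if (!is.null(predicate) && !isTRUE(predicate(chain))) next
        inner <- chain[[length(chain)]]
        row <- lapply(select, function(p) {
          vals <- resolve_path_values(inner, p)
          if (length(vals) > 0L) vals[[1]] else NULL
        })
        rows[[length(rows) + 1L]] <- row
        prov <- c(prov, format(v$uid))
      }
    }
  }
  result_set(columns, rows, prov)
}

#' Order-independent row signature of a result set
#'
#' Serializes every (row, provenance uid) pair deterministically and sorts,
#' so two result sets can be compared as multisets.
#'
#' @param rs A `result_set`.
#' @return Sorted character vector, one element per row.
#' @export
resultset_signature <- function(rs) {
  sigs <- vapply(seq_along(rs$rows), function(i) {
    cells <- vapply(rs$columns, function(cn) {
      v <- rs$rows[[i]][[cn]]
      if (is.null(v)) return("~")
      n <- value_as_number(v)
      if (!is.null(n)) return(format_num(n))
      s <- value_as_string(v)
      if (!is.null(s)) return(s)
      composition_to_json(rm_node("x", value = v))
    }, character(1))
    paste(c(rs$provenance[i], cells), collapse = "|")
  }, character(1))
  sort(sigs)
}

#' Build a lagged read replica
#'
#' Replays onto a fresh store exactly the record creations and contributions
#' with commit time at or before `now - lag`, in commit order -- the
#' population ("multi") use case accepts a bounded lag behind live
#' single-record data.
#'
#' @param store Source `VersionStore`.
#' @param lag Lag in seconds.
#' @param now Cut-off reference time; defaults to the latest event in the
#'   source log.
#' @return A new `VersionStore`.
#' @export
replicate_to_multi <- function(store, lag = 0, now = NULL) {
  lines <- store$serialize_state()
  records <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  times <- vapply(records, function(r) {
    as.numeric(parse_ehr_time(if (identical(r$event, "create_ehr")) r$time else r$commit_time))
  }, numeric(1))
  if (is.null(now)) now <- if (length(times) > 0L) max(times) else 0
  now <- if (inherits(now, "POSIXct")) as.numeric(now) else as.numeric(now)
  cutoff <- now - as.numeric(lag)
  replica <- version_store(system_id = store$system_id())
  for (i in seq_along(records)) {
    if (times[i] <= cutoff) replica$ingest_record(records[[i]])
  }
  replica
}
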