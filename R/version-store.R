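#' @title Append-only versioned storage with atomic contribution commits
#'
#' @description
#' A `VersionStore` keeps, per health record, a set of versioned objects whose
#' full history is append-only: committing never mutates or removes an existing
#' version, and logical deletion adds a new version marked `deleted`. All
#' changes enter through atomic contributions -- audited change sets of one or
#' more versions -- and every commit updates a write-through metadata cache
#' (latest modification time + latest contribution id) that feeds HTTP cache
#' validators downstream.
#'
#' Durability is an optional newline-delimited JSON commit log: one JSON object
#' per record-creation or contribution event, replayable with
#' [version_store_from_log()]. The log is byte-deterministic given the same
#' inputs, which makes the append-only property directly checkable as a prefix
#' property on serialized state.
#'
#' @name version_store
NULL

new_contribution <- function(id, ehr_id, committer_id, commit_time, description,
                             version_uids, archetype_ids, template_ids,
                             lifecycles = character(0)) {
  structure(list(id = id, ehr_id = ehr_id, committer_id = committer_id,
                 commit_time = commit_time, description = description,
                 version_uids = version_uids, archetype_ids = archetype_ids,
                 template_ids = template_ids, lifecycles = lifecycles),
            class = "contribution")
}

#' @export
print.contribution <- function(x, ...) {
  cat(sprintf("<contribution> %s on ehr:%s by %s (%d version%s)\n",
              x$id, x$ehr_id, x$committer_id, length(x$version_uids),
              if (length(x$version_uids) == 1L) "" else "s"))
  invisible(x)
}

change_types <- c("creation", "amendment", "deleted", "attestation")

#' Create a version store
#'
#' @param system_id Deployment identifier stamped as `creating_system_id` into
#'   every version uid minted locally.
#' @param validator Optional `function(rm_node) -> validation_report` applied
#'   to every version payload before commit (see [make_validator()]). A report
#'   with findings rejects the whole contribution.
#' @param on_commit Optional `function(contribution)` called once after each
#'   successful commit (used to publish trigger events).
#' @param clock `function() -> POSIXct` supplying commit times when the caller
#'   does not; defaults to [Sys.time()].
#' @return A `VersionStore` R6 object.
#' @examples
#' st <- version_store("test2.eee.mi.imt.liu.se")
#' id <- st$create_ehr("12344321")
#' comp <- rm_node("composition", "openEHR-EHR-COMPOSITION.encounter.v1",
#'                 children = list(rm_node("context", value = leaf_text("demo"))))
#' ctb <- st$commit_contribution(id,
#'   list(list(change_type = "creation", data = comp)),
#'   audit = list(committer_id = "dr_who", description = "first note"))
#' st$all_version_ids(id, ctb$version_uids[[1]]$object_id)
#' @export
version_store <- function(system_id = "ehr.example.org", validator = NULL,
                          on_commit = NULL, clock = Sys.time) {
  VersionStore$new(system_id = system_id, validator = validator,
                   on_commit = on_commit, clock = clock)
}

#' @rdname version_store
#' @export
VersionStore <- R6::R6Class("VersionStore",
  public = list(
    #' @description See [version_store()].
    #' @param system_id,validator,on_commit,clock See [version_store()].
    initialize = function(system_id = "ehr.example.org", validator = NULL,
                          on_commit = NULL, clock = Sys.time) {
      private$system_id_ <- system_id
      private$validator <- validator
      private$on_commit <- on_commit
      private$clock <- clock
      private$ehrs <- new.env(parent = emptyenv())
      private$meta_cache <- new.env(parent = emptyenv())
    },

    #' @description Create a health record.
    #' @param ehr_id Optional id; minted when absent. Must not contain
    #'   `/ : @ #`.
    #' @param time Optional creation time.
    #' @return The record id (string).
    create_ehr = function(ehr_id = NULL, time = NULL) {
      if (is.null(ehr_id)) {
        repeat {
          ehr_id <- mint_hex(12L)
          if (!self$has_ehr(ehr_id)) break
        }
      }
      if (!valid_ehr_id(ehr_id)) {
        stop_ehrest("bad_request", sprintf("invalid ehr id '%s': must be non-empty without / : @ #", ehr_id))
      }
      if (self$has_ehr(ehr_id)) stop_ehrest("conflict", sprintf("ehr '%s' already exists", ehr_id))
      time <- time %||% private$clock()
      genesis <- paste0("genesis-", mint_hex(8L))
      assign(ehr_id, list(objects = list(), contribution_idx = integer(0)), envir = private$ehrs)
      assign(ehr_id, list(ehr_id = ehr_id, last_modified = time, last_contribution_id = genesis),
             envir = private$meta_cache)
      private$append_log(list(event = "create_ehr", ehr_id = ehr_id,
                              time = format_log_time(time), genesis_id = genesis))
      ehr_id
    },

    #' @description Does a record exist?
    #' @param ehr_id Record id.
    has_ehr = function(ehr_id) exists(ehr_id, envir = private$ehrs, inherits = FALSE),

    #' @description All record ids, sorted.
    ehr_ids = function() sort(ls(private$ehrs)),

    #' @description Object ids of a record, in creation order.
    #' @param ehr_id Record id.
    object_ids = function(ehr_id) {
      names(private$get_ehr(ehr_id)$objects)
    },

    #' @description Commit an atomic contribution: all versions stored or none.
    #'
    #' Creations mint a fresh object id and tree id `"1"`; amendments,
    #' deletions and attestations must name the current latest version of
    #' their object as `preceding_uid` (anything else is a stale-update
    #' conflict) and get the next trunk tree id. Validation failures and
    #' conflicts leave the store untouched.
    #' @param ehr_id Record id.
    #' @param specs List of version specs:
    #'   `list(object_id?, preceding_uid?, change_type, lifecycle?, data?,
    #'   attestation_proof?)`.
    #' @param audit `list(committer_id=, description=)`.
    #' @param commit_time Optional `POSIXct`; defaults to the store clock.
    #' @return The committed `contribution`.
    commit_contribution = function(ehr_id, specs, audit, commit_time = NULL) {
      ehr <- private$get_ehr(ehr_id)
      if (length(specs) == 0L) stop_ehrest("bad_request", "a contribution must contain at least one version")
      committer <- audit$committer_id %||% "anonymous"
      description <- audit$description %||% ""
      commit_time <- commit_time %||% private$clock()
      contribution_id <- mint_object_id()

      staged <- list()            # new versions, appended only on full success
      staged_latest <- list()     # object_id -> staged latest uid (for multi-spec commits)
      archetype_ids <- character(0)
      template_ids <- character(0)

      latest_uid_of <- function(object_id) {
        if (!is.null(staged_latest[[object_id]])) return(staged_latest[[object_id]])
        vs <- ehr$objects[[object_id]]
        if (is.null(vs) || length(vs) == 0L) return(NULL)
        vs[[length(vs)]]$uid
      }
      next_tree_id <- function(object_id) {
        vs <- ehr$objects[[object_id]] %||% list()
        trunk <- 0L
        for (v in vs) {
          first <- as.integer(strsplit(v$uid$version_tree_id, ".", fixed = TRUE)[[1]][1])
          trunk <- max(trunk, first)
        }
        for (v in staged) if (v$uid$object_id == object_id) {
          trunk <- max(trunk, as.integer(strsplit(v$uid$version_tree_id, ".", fixed = TRUE)[[1]][1]))
        }
        as.character(trunk + 1L)
      }

      for (i in seq_along(specs)) {
        sp <- specs[[i]]
        ct <- sp$change_type
        if (is.null(ct) || !ct %in% change_types) {
          stop_ehrest("bad_request", sprintf("spec %d: unknown change_type '%s'", i, ct %||% "<missing>"))
        }
        lifecycle <- sp$lifecycle %||% "complete"
        if (!lifecycle %in% c("complete", "incomplete")) {
          stop_ehrest("bad_request", sprintf("spec %d: lifecycle must be complete or incomplete", i))
        }
        if (ct == "creation") {
          if (!is.null(sp$preceding_uid)) stop_ehrest("bad_request", sprintf("spec %d: creation cannot name a preceding version", i))
          if (is.null(sp$data)) stop_ehrest("bad_request", sprintf("spec %d: creation requires data", i))
          object_id <- sp$object_id
          if (is.null(object_id)) {
            repeat {
              object_id <- mint_object_id()
              if (is.null(ehr$objects[[object_id]]) && is.null(staged_latest[[object_id]])) break
            }
          } else if (!is.null(ehr$objects[[object_id]]) || !is.null(staged_latest[[object_id]])) {
            stop_ehrest("conflict", sprintf("spec %d: object '%s' already exists", i, object_id))
          }
          tree <- "1"
          preceding <- NULL
        } else {
          prec <- sp$preceding_uid
          if (is.null(prec)) stop_ehrest("bad_request", sprintf("spec %d: %s requires preceding_uid", i, ct))
          prec <- if (inherits(prec, "version_uid")) prec else parse_version_uid(prec)
          object_id <- prec$object_id
          cur <- latest_uid_of(object_id)
          if (is.null(cur)) stop_ehrest("not_found", sprintf("spec %d: object '%s' not found in ehr '%s'", i, object_id, ehr_id))
          if (format(cur) != format(prec)) {
            stop_ehrest("conflict", sprintf("spec %d: stale preceding version '%s' (current is '%s')",
                                            i, format(prec), format(cur)))
          }
          if (ct == "deleted" && !is.null(sp$data)) {
            stop_ehrest("bad_request", sprintf("spec %d: a deleted version carries no data", i))
          }
          if (ct == "amendment" && is.null(sp$data)) {
            stop_ehrest("bad_request", sprintf("spec %d: amendment requires data", i))
          }
          tree <- next_tree_id(object_id)
          preceding <- prec
        }
        if (!is.null(sp$data)) {
          if (!inherits(sp$data, "rm_node")) stop_ehrest("bad_request", sprintf("spec %d: data must be an rm_node", i))
          if (!is.null(private$validator)) {
            rep <- private$validator(sp$data)
            if (!is_valid(rep)) {
              msgs <- vapply(rep$findings, function(f) sprintf("[%s] %s: %s", f$level, f$path, f$message), character(1))
              stop_ehrest("validation_error", sprintf("spec %d rejected: %s", i, paste(msgs, collapse = "; ")))
            }
            archetype_ids <- c(archetype_ids, rep$archetype_ids)
            template_ids <- c(template_ids, rep$template_ids %||% character(0))
          } else {
            archetype_ids <- c(archetype_ids, collect_archetype_ids(sp$data))
          }
        }
        uid <- version_uid(object_id, private$system_id_, tree)
        staged[[length(staged) + 1L]] <- list(
          uid = uid, preceding_uid = preceding, data = sp$data %||% NULL,
          change_type = ct, lifecycle = lifecycle, commit_time = commit_time,
          contribution_id = contribution_id,
          attestation_proof = sp$attestation_proof %||% NULL
        )
        staged_latest[[object_id]] <- uid
      }

      # all specs valid: apply atomically
      for (v in staged) {
        oid <- v$uid$object_id
        if (is.null(ehr$objects[[oid]])) ehr$objects[[oid]] <- list()
        ehr$objects[[oid]][[length(ehr$objects[[oid]]) + 1L]] <- v
      }
      private$seq <- private$seq + 1L
      contribution <- new_contribution(
        id = contribution_id, ehr_id = ehr_id, committer_id = committer,
        commit_time = commit_time, description = description,
        version_uids = lapply(staged, `[[`, "uid"),
        archetype_ids = unique(archetype_ids), template_ids = unique(template_ids),
        lifecycles = vapply(staged, `[[`, character(1), "lifecycle")
      )
      private$contributions[[length(private$contributions) + 1L]] <- contribution
      ehr$contribution_idx <- c(ehr$contribution_idx, length(private$contributions))
      assign(ehr_id, ehr, envir = private$ehrs)
      # write-through metadata cache
      assign(ehr_id, list(ehr_id = ehr_id, last_modified = commit_time,
                          last_contribution_id = contribution_id),
             envir = private$meta_cache)
      private$append_log(contribution_log_record(contribution, staged))
      if (!is.null(private$on_commit)) private$on_commit(contribution)
      contribution
    },

    #' @description Fetch one version of an object.
    #' @param ehr_id,object_id Identifiers.
    #' @param selector A full uid string (`a::b::c`), a `version_uid`,
    #'   `"latest_version"`, or a timestamp (string or `POSIXct`) meaning "the
    #'   version current at that instant".
    #' @return The version (list with `uid`, `preceding_uid`, `data`,
    #'   `change_type`, `lifecycle`, `commit_time`, `contribution_id`).
    get_version = function(ehr_id, object_id, selector = "latest_version") {
      private$db_reads <- private$db_reads + 1L
      vs <- private$get_object(ehr_id, object_id)
      if (inherits(selector, "version_uid") ||
          (is_string(selector) && grepl("::", selector, fixed = TRUE))) {
        want <- uid_chr(selector)
        for (v in vs) if (format(v$uid) == want) return(v)
        stop_ehrest("not_found", sprintf("no version '%s' of object '%s'", want, object_id))
      }
      if (identical(selector, "latest_version")) return(vs[[length(vs)]])
      t <- if (inherits(selector, "POSIXct")) selector else parse_ehr_time(selector)
      hit <- NULL
      for (v in vs) if (v$commit_time <= t) hit <- v
      if (is.null(hit)) {
        stop_ehrest("not_found", sprintf("object '%s' had no version at %s", object_id, format_ehr_time(t)))
      }
      hit
    },

    #' @description All version uids of an object, in commit order.
    #' @param ehr_id,object_id Identifiers.
    all_version_ids = function(ehr_id, object_id) {
      private$db_reads <- private$db_reads + 1L
      lapply(private$get_object(ehr_id, object_id), `[[`, "uid")
    },

    #' @description Page through a record's contributions.
    #' @param ehr_id Record id.
    #' @param start,end 1-based inclusive slice bounds (defaults 1 and 20).
    #' @param descending Most recent first (default `TRUE`).
    list_contributions = function(ehr_id, start = 1L, end = 20L, descending = TRUE) {
      private$db_reads <- private$db_reads + 1L
      ehr <- private$get_ehr(ehr_id)
      start <- as.integer(start); end <- as.integer(end)
      if (is.na(start) || is.na(end) || start < 1L || end < start) {
        stop_ehrest("bad_request", sprintf("invalid contribution range [%s, %s]", start, end))
      }
      seqs <- ehr$contribution_idx
      if (descending) seqs <- rev(seqs)
      if (start > length(seqs)) return(list())
      seqs <- seqs[seq.int(start, min(end, length(seqs)))]
      lapply(seqs, function(i) private$contributions[[i]])
    },

    #' @description Fetch one contribution by id.
    #' @param ehr_id Record id.
    #' @param contribution_id Contribution id.
    get_contribution = function(ehr_id, contribution_id) {
      private$db_reads <- private$db_reads + 1L
      ehr <- private$get_ehr(ehr_id)
      for (i in ehr$contribution_idx) {
        if (private$contributions[[i]]$id == contribution_id) return(private$contributions[[i]])
      }
      stop_ehrest("not_found", sprintf("no contribution '%s' in ehr '%s'", contribution_id, ehr_id))
    },

    #' @description Latest modification time and contribution id for a record,
    #'   served from the write-through RAM cache when warm (a warm hit performs
    #'   no store read).
    #' @param ehr_id Record id.
    metadata = function(ehr_id) {
      if (exists(ehr_id, envir = private$meta_cache, inherits = FALSE)) {
        return(get(ehr_id, envir = private$meta_cache))
      }
      # cold: one database read, then cache
      private$db_reads <- private$db_reads + 1L
      ehr <- private$get_ehr(ehr_id)
      n <- length(ehr$contribution_idx)
      if (n == 0L) stop_ehrest("internal", sprintf("no metadata for ehr '%s'", ehr_id))
      last <- private$contributions[[ehr$contribution_idx[n]]]
      entry <- list(ehr_id = ehr_id, last_modified = last$commit_time,
                    last_contribution_id = last$id)
      assign(ehr_id, entry, envir = private$meta_cache)
      entry
    },

    #' @description Drop a record's cached metadata (forces a cold read).
    #' @param ehr_id Record id.
    evict_metadata = function(ehr_id) {
      if (exists(ehr_id, envir = private$meta_cache, inherits = FALSE)) {
        rm(list = ehr_id, envir = private$meta_cache)
      }
      invisible(NULL)
    },

    #' @description Number of raw store reads performed so far (instrumentation
    #'   used to verify that cache hits and debug runs touch no data).
    read_count = function() private$db_reads,

    #' @description The deployment's `creating_system_id`.
    system_id = function() private$system_id_,

    #' @description Serialized store state: the commit log, one JSON object per
    #'   record-creation or contribution event, in commit order. Appending is
    #'   the only mutation, so earlier states are byte prefixes of later ones.
    serialize_state = function() {
      if (private$log_n == 0L) character(0)
      else unlist(private$log_lines[seq_len(private$log_n)], use.names = FALSE)
    },

    #' @description Write the commit log to a file.
    #' @param path File path.
    export_log = function(path) {
      writeLines(self$serialize_state(), path)
      invisible(path)
    },

    #' @description Apply one parsed commit-log record, preserving its original
    #'   identifiers. Used by log replay and by replication subscribers; normal
    #'   writes go through `commit_contribution()`.
    #' @param record A parsed log record (list).
    ingest_record = function(record) {
      if (identical(record$event, "create_ehr")) {
        if (self$has_ehr(record$ehr_id)) stop_ehrest("conflict", sprintf("ehr '%s' already exists", record$ehr_id))
        t <- parse_ehr_time(record$time)
        assign(record$ehr_id, list(objects = list(), contribution_idx = integer(0)), envir = private$ehrs)
        assign(record$ehr_id, list(ehr_id = record$ehr_id, last_modified = t,
                                   last_contribution_id = record$genesis_id),
               envir = private$meta_cache)
        private$append_log(record)
        return(invisible(NULL))
      }
      stopifnot(identical(record$event, "contribution"))
      ehr <- private$get_ehr(record$ehr_id)
      t <- parse_ehr_time(record$commit_time)
      versions <- lapply(record$versions, function(vr) {
        list(
          uid = parse_version_uid(vr$uid),
          preceding_uid = if (!is.null(vr$preceding_uid)) parse_version_uid(vr$preceding_uid) else NULL,
          data = if (!is.null(vr$data)) list_to_node(vr$data) else NULL,
          change_type = vr$change_type, lifecycle = vr$lifecycle,
          commit_time = t, contribution_id = record$id,
          attestation_proof = vr$attestation_proof %||% NULL
        )
      })
      for (v in versions) {
        oid <- v$uid$object_id
        if (is.null(ehr$objects[[oid]])) ehr$objects[[oid]] <- list()
        ehr$objects[[oid]][[length(ehr$objects[[oid]]) + 1L]] <- v
      }
      private$seq <- private$seq + 1L
      contribution <- new_contribution(
        id = record$id, ehr_id = record$ehr_id, committer_id = record$committer_id,
        commit_time = t, description = record$description,
        version_uids = lapply(versions, `[[`, "uid"),
        archetype_ids = unlist(record$archetype_ids) %||% character(0),
        template_ids = unlist(record$template_ids) %||% character(0),
        lifecycles = vapply(versions, `[[`, character(1), "lifecycle")
      )
      private$contributions[[length(private$contributions) + 1L]] <- contribution
      ehr$contribution_idx <- c(ehr$contribution_idx, length(private$contributions))
      assign(record$ehr_id, ehr, envir = private$ehrs)
      assign(record$ehr_id, list(ehr_id = record$ehr_id, last_modified = t,
                                 last_contribution_id = record$id),
             envir = private$meta_cache)
      private$append_log(record)
      if (!is.null(private$on_commit)) private$on_commit(contribution)
      invisible(NULL)
    },

    #' @description Latest version of every object in a record, in object
    #'   creation order. Used by query execution.
    #' @param ehr_id Record id.
    latest_versions = function(ehr_id) {
      private$db_reads <- private$db_reads + 1L
      ehr <- private$get_ehr(ehr_id)
      lapply(ehr$objects, function(vs) vs[[length(vs)]])
    },

    #' @description Print a summary.
    print = function() {
      ids <- self$ehr_ids()
      cat(sprintf("<VersionStore> %s: %d ehr(s), %d contribution(s)\n",
                  private$system_id_, length(ids), length(private$contributions)))
      invisible(self)
    }
  ),
  private = list(
    system_id_ = NULL, validator = NULL, on_commit = NULL, clock = NULL,
    ehrs = NULL, meta_cache = NULL,
    contributions = list(), seq = 0L, db_reads = 0L,
    log_lines = list(), log_n = 0L,
    get_ehr = function(ehr_id) {
      if (!self$has_ehr(ehr_id)) stop_ehrest("not_found", sprintf("no ehr '%s'", ehr_id))
      get(ehr_id, envir = private$ehrs)
    },
    get_object = function(ehr_id, object_id) {
      ehr <- private$get_ehr(ehr_id)
      vs <- ehr$objects[[object_id]]
      if (is.null(vs)) stop_ehrest("not_found", sprintf("no object '%s' in ehr '%s'", object_id, ehr_id))
      vs
    },
    append_log = function(record) {
      private$log_n <- private$log_n + 1L
      private$log_lines[[private$log_n]] <-
        as.character(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA, null = "null"))
    }
  )
)

format_log_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")

contribution_log_record <- function(contribution, versions) {
  list(
    event = "contribution",
    id = contribution$id,
    ehr_id = contribution$ehr_id,
    committer_id = contribution$committer_id,
    commit_time = format_log_time(contribution$commit_time),
    description = contribution$description,
    versions = lapply(versions, function(v) {
      out <- list(uid = format(v$uid))
      if (!is.null(v$preceding_uid)) out$preceding_uid <- format(v$preceding_uid)
      out$change_type <- v$change_type
      out$lifecycle <- v$lifecycle
      if (!is.null(v$data)) out$data <- node_to_list(v$data)
      if (!is.null(v$attestation_proof)) out$attestation_proof <- v$attestation_proof
      out
    }),
    archetype_ids = as.list(contribution$archetype_ids),
    template_ids = as.list(contribution$template_ids)
  )
}

#' Rebuild a store by replaying a commit log
#'
#' @param lines Character vector of commit-log lines (or a file path via
#'   `file`).
#' @param file Path to a commit-log file (alternative to `lines`).
#' @inheritParams version_store
#' @return A `VersionStore` whose serialized state equals the input log.
#' @export
version_store_from_log <- function(lines = NULL, file = NULL,
                                   system_id = "ehr.example.org",
                                   validator = NULL, on_commit = NULL) {
  if (is.null(lines)) lines <- readLines(file)
  st <- version_store(system_id = system_id, validator = validator, on_commit = on_commit)
  for (ln in lines) {
    st$ingest_record(jsonlite::fromJSON(ln, simplifyVector = FALSE))
  }
  st
}
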