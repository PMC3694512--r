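#' @title Commit-event trigger messaging
#'
#' @description
#' Every successful contribution commit publishes exactly one trigger message
#' to topic `/contributions/{ehr_id}`. Messages carry identifiers only --
#' patient, committer, changed resource URIs, and the archetype/template ids
#' the validators collected -- never clinical content; listeners (decision
#' support, replication, export) fetch details over the normal resource URIs.
#' The in-process bus delivers to pattern-matched subscriptions (`*` matches
#' one topic segment, `#` any trailing segments) and serializes messages as
#' STOMP-style text frames at the wire boundary.
#'
#' @name trigger_bus
NULL

#' Match a topic pattern
#'
#' `*` matches exactly one path segment; `#` (only as the final segment)
#' matches zero or more trailing segments; anything else matches literally.
#'
#' @param pattern Pattern path, e.g. `"/contributions/*"`.
#' @param topic Concrete topic path.
#' @return `TRUE` or `FALSE`.
#' @examples
#' topic_match("/contributions/*", "/contributions/12344321")
#' topic_match("/contributions/#", "/contributions/a/b")
#' @export
topic_match <- function(pattern, topic) {
  validate_topic_pattern(pattern)
  ps <- strsplit(sub("^/", "", pattern), "/", fixed = TRUE)[[1]]
  ts <- strsplit(sub("^/", "", topic), "/", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(ps)) {
    p <- ps[i]
    if (p == "#") return(TRUE)  # validated to be last
    if (i > length(ts)) return(FALSE)
    if (p != "*" && p != ts[i]) return(FALSE)
    i <- i + 1L
  }
  length(ts) == length(ps)
}

validate_topic_pattern <- function(pattern) {
  if (!is_string(pattern) || !startsWith(pattern, "/")) {
    stop_ehrest("bad_request", "topic pattern must be a string starting with '/'")
  }
  segs <- strsplit(sub("^/", "", pattern), "/", fixed = TRUE)[[1]]
  if (length(segs) == 0L || any(!nzchar(segs))) {
    stop_ehrest("bad_request", sprintf("malformed topic pattern '%s': empty segment", pattern))
  }
  hash <- which(segs == "#")
  if (length(hash) > 1L || (length(hash) == 1L && hash != length(segs))) {
    stop_ehrest("bad_request", sprintf("malformed topic pattern '%s': '#' may only be the final segment", pattern))
  }
  invisible(pattern)
}

#' Construct a trigger message
#' @param topic Topic path.
#' @param headers Named list of header values (character or character vectors;
#'   vectors are carried as lists and comma-joined on the wire).
#' @return A `trigger_message`.
#' @export
trigger_message <- function(topic, headers = list()) {
  structure(list(topic = topic, headers = headers, body = ""),
            class = "trigger_message")
}

#' @export
print.trigger_message <- function(x, ...) {
  cat(sprintf("<trigger_message> %s (%d header%s)\n", x$topic, length(x$headers),
              if (length(x$headers) == 1L) "" else "s"))
  invisible(x)
}

# Header-value escaping for the text frame. STOMP escapes backslash, newline
# and colon; commas are escaped too because list-valued headers are
# comma-joined on the wire.
escape_header <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub(":", "\\c", x, fixed = TRUE)
  gsub(",", "\\m", x, fixed = TRUE)
}

unescape_header <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    chars <- strsplit(x[k], "", fixed = TRUE)[[1]]
    buf <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        buf <- c(buf, switch(nxt, "n" = "\n", "c" = ":", "m" = ",", "\\" = "\\",
                             stop_ehrest("parse_error", sprintf("bad escape '\\%s' in frame header", nxt))))
        i <- i + 2L
      } else {
        buf <- c(buf, chars[i]); i <- i + 1L
      }
    }
    out[k] <- paste(buf, collapse = "")
  }
  out
}

#' Serialize / parse a trigger message as a text frame
#'
#' STOMP-style MESSAGE frame: a command line, `key:value` header lines, one
#' blank line, then the (empty) body. List-valued headers are comma-joined;
#' commas inside values are escaped so the round trip is exact.
#'
#' @param msg A `trigger_message`.
#' @return `serialize_frame()`: a single NUL-free string.
#' @export
serialize_frame <- function(msg) {
  hdrs <- c(list(topic = msg$topic), msg$headers)
  lines <- vapply(seq_along(hdrs), function(i) {
    v <- hdrs[[i]]
    vals <- vapply(as.character(unlist(v) %||% character(0)), escape_header, character(1))
    paste0(escape_header(names(hdrs)[i]), ":", paste(vals, collapse = ","))
  }, character(1))
  paste(c("MESSAGE", lines, "", msg$body), collapse = "\n")
}

#' @rdname serialize_frame
#' @param text A serialized frame.
#' @return `parse_frame()`: a `trigger_message`.
#' @export
parse_frame <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 2L || lines[1] != "MESSAGE") {
    stop_ehrest("parse_error", "not a MESSAGE frame")
  }
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop_ehrest("parse_error", "frame has no blank line separating headers from body")
  headers <- list()
  topic <- NULL
  for (ln in lines[seq.int(2L, blank - 1L)]) {
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 1L) stop_ehrest("parse_error", sprintf("malformed header line '%s'", ln))
    key <- unescape_header(substr(ln, 1L, colon - 1L))
    raw <- substr(ln, colon + 1L, nchar(ln))
    # split on unescaped commas
    parts <- character(0); buf <- ""
    chars <- strsplit(raw, "", fixed = TRUE)[[1]]
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) { buf <- paste0(buf, chars[i], chars[i + 1L]); i <- i + 2L; next }
      if (chars[i] == ",") { parts <- c(parts, buf); buf <- "" } else buf <- paste0(buf, chars[i])
      i <- i + 1L
    }
    parts <- c(parts, buf)
    vals <- unescape_header(parts)
    if (key == "topic") topic <- vals[1]
    else headers[[key]] <- if (length(vals) == 1L) vals else as.list(vals)
  }
  if (is.null(topic)) stop_ehrest("parse_error", "frame lacks a topic header")
  msg <- trigger_message(topic, headers)
  msg$body <- paste(lines[seq.int(blank + 1L, length(lines))], collapse = "\n")
  msg
}

#' Create a trigger bus
#' @return A `TriggerBus` R6 object.
#' @export
trigger_bus <- function() TriggerBus$new()

#' @rdname trigger_bus
#' @export
TriggerBus <- R6::R6Class("TriggerBus",
  public = list(
    #' @description Create an empty bus.
    initialize = function() {},

    #' @description Subscribe a callback to a topic pattern.
    #' @param pattern Topic pattern (validated now; malformed patterns error).
    #' @param callback `function(trigger_message)`.
    #' @param id Optional subscription id.
    #' @return The subscription id.
    subscribe = function(pattern, callback, id = NULL) {
      validate_topic_pattern(pattern)
      id <- id %||% paste0("sub-", length(private$subs) + 1L)
      private$subs[[id]] <- list(pattern = pattern, callback = callback)
      id
    },

    #' @description Remove a subscription.
    #' @param id Subscription id.
    unsubscribe = function(id) {
      private$subs[[id]] <- NULL
      invisible(NULL)
    },

    #' @description Deliver a message to every matching subscription. A
    #'   failing callback is logged and isolated; other deliveries proceed.
    #' @param msg A `trigger_message`.
    #' @return Number of successful deliveries.
    publish = function(msg) {
      delivered <- 0L
      for (id in names(private$subs)) {
        sub <- private$subs[[id]]
        if (!topic_match(sub$pattern, msg$topic)) next
        ok <- tryCatch({ sub$callback(msg); TRUE },
                       error = function(e) {
                         private$failures <- c(private$failures,
                                               sprintf("%s: %s", id, conditionMessage(e)))
                         FALSE
                       })
        if (ok) delivered <- delivered + 1L
      }
      delivered
    },

    #' @description Build and publish the single trigger message for a commit.
    #'   Headers identify the patient, committer, contribution URI, changed
    #'   resource URIs, archetype ids and template ids -- identifiers only.
    #' @param contribution A `contribution` from the version store.
    #' @return Number of successful deliveries.
    publish_commit = function(contribution) {
      msg <- trigger_message(
        topic = paste0("/contributions/", contribution$ehr_id),
        headers = list(
          ehr_id = contribution$ehr_id,
          committer_id = contribution$committer_id,
          contribution_uri = sprintf("/ehr:%s/contributions/%s/",
                                     contribution$ehr_id, contribution$id),
          changed_resource_uris = as.list(vapply(contribution$version_uids, function(u) {
            sprintf("/ehr:%s/%s", contribution$ehr_id, format(u))
          }, character(1))),
          archetype_ids = as.list(contribution$archetype_ids),
          template_ids = as.list(contribution$template_ids),
          lifecycles = as.list(contribution$lifecycles %||% character(0))
        )
      )
      self$publish(msg)
    },

    #' @description Callback failures logged so far.
    failure_log = function() private$failures,

    #' @description Print a summary.
    print = function() {
      cat(sprintf("<TriggerBus> %d subscription(s)\n", length(private$subs)))
      invisible(self)
    }
  ),
  private = list(subs = list(), failures = character(0))
)

#' Replication subscriber: apply every commit event to a replica store
#'
#' The returned callback fetches the full contribution from the source store
#' (trigger messages carry identifiers only) and ingests it -- original uids
#' and ids preserved -- into the replica. Subscribing it to
#' `/contributions/#` makes the replica's serialized state track the source's.
#'
#' @param source,replica `VersionStore`s.
#' @return `function(trigger_message)`.
#' @export
make_replication_subscriber <- function(source, replica) {
  function(msg) {
    ehr_id <- msg$headers$ehr_id
    if (!replica$has_ehr(ehr_id)) {
      # replay the source's creation record for this ehr
      for (ln in source$serialize_state()) {
        rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
        if (identical(rec$event, "create_ehr") && identical(rec$ehr_id, ehr_id)) {
          replica$ingest_record(rec)
          break
        }
      }
    }
    cid <- sub(".*/contributions/([^/]+)/$", "\\1", msg$headers$contribution_uri)
    for (ln in source$serialize_state()) {
      rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
      if (identical(rec$event, "contribution") && identical(rec$id, cid)) {
        replica$ingest_record(rec)
        return(invisible(NULL))
      }
    }
    stop_ehrest("not_found", sprintf("contribution '%s' not found in source store", cid))
  }
}
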