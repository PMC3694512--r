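#!/usr/bin/env Rscript
# Thin HTTP wrapper over ehrest::ehr_server()$dispatch():
#   Rscript scripts/serve.R --port 8080 --host ehr.example.org --seed 1 [--patients 20]
# With --patients > 0 the server starts pre-populated with a synthetic cohort,
# which is handy for exploring the URI grammar with curl.

suppressPackageStartupMessages({
  library(ehrest)
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    stop("serving over a socket requires the 'httpuv' package")
  }
})

args <- commandArgs(trailingOnly = TRUE)
port <- 8080L; host_name <- "ehr.example.org"; seed <- 1L; patients <- 0L
i <- 1L
while (i <= length(args)) {
  key <- args[i]
  val <- args[i + 1L]
  switch(key,
    "--port" = { port <- as.integer(val) },
    "--host" = { host_name <- val },
    "--seed" = { seed <- as.integer(val) },
    "--patients" = { patients <- as.integer(val) },
    stop("unknown argument: ", key))
  i <- i + 2L
}

set.seed(seed)
srv <- ehr_server(host = host_name)
if (patients > 0L) {
  srv <- generate_population(population_spec(n_patients = patients, seed = seed), srv)
  cat(sprintf("populated %d synthetic patient record(s)\n", patients))
}

app <- list(
  call = function(req) {
    headers <- list(
      `Accept` = req$HTTP_ACCEPT,
      `Content-Type` = req$CONTENT_TYPE,
      `If-None-Match` = req$HTTP_IF_NONE_MATCH,
      `If-Match` = req$HTTP_IF_MATCH,
      `Referer` = req$HTTP_REFERER,
      `User-Agent` = req$HTTP_USER_AGENT,
      `X-Committer` = req$HTTP_X_COMMITTER
    )
    headers <- Filter(Negate(is.null), headers)
    body <- if (!is.null(req$rook.input)) req$rook.input$read_lines() else NULL
    if (!is.null(body)) body <- paste(body, collapse = "\n")
    uri <- req$PATH_INFO
    if (!is.null(req$QUERY_STRING) && nzchar(req$QUERY_STRING)) {
      uri <- paste0(uri, req$QUERY_STRING)
    }
    resp <- srv$dispatch(req$REQUEST_METHOD, uri, headers = headers, body = body)
    list(status = resp$status,
         headers = as.list(resp$headers),
         body = resp$body %||% "")
  }
)
`%||%` <- function(a, b) if (is.null(a)) b else a

cat(sprintf("ehrest serving on http://127.0.0.1:%d/ (system id %s)\n", port, host_name))
httpuv::runServer("127.0.0.1", port, app)
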