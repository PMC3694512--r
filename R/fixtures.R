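#' Shipped constraint documents
#'
#' The package ships two plain-text constraint documents under
#' `inst/extdata/`: a blood-pressure-bearing encounter archetype
#' (`bp_archetype.json`, permissive magnitude ranges 0--1000 mm[Hg]) and a
#' narrowing template (`bp_template.json`) that tightens the ranges and makes
#' the diastolic reading mandatory. They drive commit validation, skeleton
#' generation and the synthetic generator's conformance guarantees. Both are
#' synthetic stand-ins authored for this package, not published archetypes.
#'
#' @return A list of `constraint_doc`s (archetype first).
#' @export
shipped_constraint_docs <- function() {
  dir <- system.file("extdata", package = "ehrest")
  list(
    read_constraint_doc(file.path(dir, "bp_archetype.json")),
    read_constraint_doc(file.path(dir, "bp_template.json"))
  )
}
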