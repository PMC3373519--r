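#' Published comparative humerus-length table
#'
#' Humeral lengths (mm) for a sample of hadrosaurid species as printed
#' in the study's comparative table.  The LACM 17712 value is itself a
#' regression estimate in the source (flagged by `estimated = TRUE`),
#' not a measurement.
#'
#' @return Data frame with `taxon`, `specimen`, `clade`, `humerus_mm`,
#'   `estimated`.
#' @export
humerus_length_table <- function() {
  read.csv(system.file("extdata", "hadrosaurid_humerus_lengths.csv",
                       package = "morphoclade"),
           stringsAsFactors = FALSE)
}

#' Transcribed lambeosaurine phylogeny (figure-derived)
#'
#' A rooted topology for the 19 lambeosaurine species, transcribed by
#' hand from the published tree figure and its description in the text.
#' Because it is a transcription rather than deposited data it should
#' be used for qualitative checks only.
#'
#' @return A rooted `phylo` object.
#' @export
lambeosaurine_tree <- function() {
  ape::read.tree(system.file("extdata",
                             "lambeosaurine_topology_transcribed.nwk",
                             package = "morphoclade"))
}

#' Transcribed lambeosaurine tip areas (figure-derived)
#'
#' Terminal distributions over the four continental areas (`E` Europe,
#' `AS` Asia, `NNA` northern North America, `SNA` southern North
#' America) for the transcribed lambeosaurine tree, assembled from the
#' localities discussed in the text.  Qualitative use only.
#'
#' @return Named list of area-code vectors (see [read_area_csv()]).
#' @export
lambeosaurine_areas <- function() {
  read_area_csv(system.file("extdata",
                            "lambeosaurine_areas_transcribed.csv",
                            package = "morphoclade"))
}
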