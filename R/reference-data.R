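# Published comparison values for the three Hawaiian gobiid species, shipped
# as plain-text tables. The raw video data behind these group statistics were
# never deposited, so these printed summaries are the reference inputs for
# derivable secondary statistics (divergence-angle summaries, threshold
# counts, percent-excess contrasts).

#' Published feeding-versus-climbing comparison table
#'
#' Per-variable mean maxima (with s.e.m. and cycle counts) for feeding and
#' climbing in *Sicyopterus stimpsoni*, and the divergence angle between the
#' two behaviors' 101-point mean kinematic profiles.
#'
#' @return data.frame with one row per kinematic variable.
#' @export
reference_feeding_climbing <- function() {
  utils::read.csv(system.file("extdata", "reference_feeding_climbing.csv",
                              package = "gobykin"),
                  stringsAsFactors = FALSE)
}

#' Published interspecific feeding mean maxima
#'
#' Feeding mean maxima (with s.e.m.) for four kinematic variables across
#' *Sicyopterus stimpsoni*, *Awaous guamensis* and *Lentipes concolor*.
#'
#' @return data.frame, one row per variable x species.
#' @export
reference_interspecific_means <- function() {
  utils::read.csv(system.file("extdata", "reference_interspecific_means.csv",
                              package = "gobykin"),
                  stringsAsFactors = FALSE)
}

#' Published interspecific profile divergence angles
#'
#' Divergence angles between feeding kinematic profiles of each suction
#' feeder and the benthic scraper, per variable.
#'
#' @return data.frame, one row per variable x species pair.
#' @export
reference_interspecific_divergence <- function() {
  utils::read.csv(system.file("extdata", "reference_interspecific_divergence.csv",
                              package = "gobykin"),
                  stringsAsFactors = FALSE)
}
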