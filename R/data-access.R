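#' Observed departure-state counts of the field study
#'
#' Per-species tallies from the tagging campaign the package emulates:
#' detected offshore flights, detected onshore flights, departures
#' determined from stopover signals without a detected flight
#' ("unrouted"), birds whose departure could not be determined, and the
#' total number of radio-tagged individuals, together with the migration
#' distance group and tag type of each species.
#'
#' @return data.frame with one row per species.
#' @examples
#' tallies <- departureStateCounts()
#' sum(tallies$offshore + tallies$onshore)          # detected flights
#' sum(tallies$offshore + tallies$onshore +
#'     tallies$departed_unrouted)                   # modeled individuals
#' @export
departureStateCounts <- function() {
    read.csv(system.file("extdata", "departure_state_counts.csv",
                         package = "migrateHMM"))
}
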