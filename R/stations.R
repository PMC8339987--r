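## IASLC lymph-node station map used by both the scenario oracle and the
## rule engine: station 1 = supraclavicular zone; 2-6 and 8-9 =
## mediastinal; 7 = subcarinal; 10-14 = hilar / intrapulmonary.

#' Map lymph-node stations to anatomical regions
#' @param stations integer vector of station numbers (1-14).
#' @return character vector of regions for each station.
#' @export
station_region <- function(stations) {
  if (length(stations) && (any(stations < 1) || any(stations > 14))) {
    stopf("lymph-node stations must lie in 1..14")
  }
  vapply(stations, function(s) {
    if (s == 1) "supraclavicular"
    else if (s == 7) "subcarinal"
    else if (s %in% c(2:6, 8:9)) "mediastinal"
    else "hilar"
  }, character(1))
}
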