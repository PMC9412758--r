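#' Pipeline and criteria configuration
#'
#' Collects every tunable policy in one object:
#'
#' * `uncertainty_policy`: `"INCLUDE"` keeps assertions hedged by uncertainty
#'   cues when evaluating criteria; `"EXCLUDE"` drops them first.
#' * `range_threshold_policy`: how an onset *range* is compared with an age
#'   threshold `T`. `"OPTIMISTIC"` (default) fires when the range lower bound
#'   is `<= T` (screening intent: "dx in 30s" qualifies for a 45-year
#'   threshold); `"STRICT"` requires the upper bound `<= T`.
#' * `colon_definition`: `"COLON_RECTAL"` (default) counts rectal cancer as
#'   colon cancer for the colorectal criteria; `"COLON"` restricts to colon.
#' * `unknown_side_counts`: whether assertions with unknown side of family
#'   count toward the same-side tallies (default `FALSE`, conservative).
#' * `comment_polyposis`: whether comment-derived (as opposed to coded)
#'   syndrome assertions can satisfy the gene/syndrome colorectal criterion
#'   (default `TRUE`).
#' * `inferred_range_participates`: whether an onset range inferred from a
#'   deceased age may satisfy an age threshold under the optimistic policy
#'   (default `TRUE`).
#' * `lexicon`: an [default_lexicon()]-shaped lexicon.
#'
#' @param uncertainty_policy `"INCLUDE"` or `"EXCLUDE"`
#' @param range_threshold_policy `"OPTIMISTIC"` or `"STRICT"`
#' @param colon_definition `"COLON_RECTAL"` or `"COLON"`
#' @param unknown_side_counts logical
#' @param comment_polyposis logical
#' @param inferred_range_participates logical
#' @param lexicon an `fhh_lexicon`
#' @return a list of class `fhh_config`
#' @export
fhh_config <- function(uncertainty_policy = c("INCLUDE", "EXCLUDE"),
                       range_threshold_policy = c("OPTIMISTIC", "STRICT"),
                       colon_definition = c("COLON_RECTAL", "COLON"),
                       unknown_side_counts = FALSE,
                       comment_polyposis = TRUE,
                       inferred_range_participates = TRUE,
                       lexicon = default_lexicon()) {
  structure(list(
    uncertainty_policy = match.arg(uncertainty_policy),
    range_threshold_policy = match.arg(range_threshold_policy),
    colon_definition = match.arg(colon_definition),
    unknown_side_counts = isTRUE(unknown_side_counts),
    comment_polyposis = isTRUE(comment_polyposis),
    inferred_range_participates = isTRUE(inferred_range_participates),
    lexicon = lexicon
  ), class = "fhh_config")
}

#' Read a configuration file
#'
#' YAML file whose keys mirror the arguments of [fhh_config()]; an optional
#' `lexicon_dir` key points at a directory written by [write_lexicon()].
#' Unset keys fall back to the defaults.
#'
#' @param path path to a YAML config file
#' @return an `fhh_config`
#' @export
read_fhh_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading a config file requires the 'yaml' package",
          class = "fhh_config_error")
  }
  raw <- yaml::read_yaml(path)
  lex <- if (!is.null(raw$lexicon_dir)) read_lexicon(raw$lexicon_dir)
         else default_lexicon()
  args <- raw[intersect(names(raw),
                        c("uncertainty_policy", "range_threshold_policy",
                          "colon_definition", "unknown_side_counts",
                          "comment_polyposis",
                          "inferred_range_participates"))]
  do.call(fhh_config, c(args, list(lexicon = lex)))
}
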