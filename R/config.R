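#' @import methods
NULL

.HINE_DEFAULTS <- list(
  tr_match = 2L, tr_mismatch = -7L, tr_indel = -7L, tr_min_score = 50L,
  period_min = 100L, period_max = 500L, min_copies = 2.0,
  redundancy_overlap = 0.50, cluster_identity = 0.70,
  flank_len = 4000L, flank_support = 0.50, flank_identity = 0.70,
  rf_window = 60L,
  ir_match = 2L, ir_mismatch = -5L, ir_indel = -7L, ir_min_score = 14L,
  ir_identity = 0.90,
  subtir_len_range = c(11L, 12L), ir_len_range = c(7L, 12L),
  ir_spacer_range = c(1L, 12L), motif_mismatch = 1L,
  ms_match = 2L, ms_mismatch = -3L, ms_indel = -5L,
  ms_unit_range = c(3L, 8L),
  linker_range = c(10L, 500L),
  empty_flank = 50L, empty_min_identity = 0.80, empty_min_coverage = 0.85,
  double_array_max_gap = 1300L,
  tsd_len_range = c(2L, 10L),
  genome_size_for_proportion = 559e6,
  rng_seed = 1L
)

#' Pipeline configuration
#'
#' Holds every numeric threshold of the pipeline: tandem-array detection
#' weights (+2/-7/-7, minimum score 50), the 100-500 bp period window and
#' minimum 2 copies, the 50\% redundancy-overlap rule, the 70\% clustering
#' identity, flank extraction length (4,000 bp) and consensus support/identity
#' floors (50\%/70\%), the 60 bp right-flank window, inverted-repeat weights
#' (+2/-5/-7, minimum score 14, 90\% identity) and subTIR/IR/spacer length
#' ranges, microsatellite weights (+2/-3/-5) and unit range, linker range,
#' empty-site thresholds (80\% identity over 85\% coverage from 50+50 bp
#' junction chimeras), the 1,300 bp double-array gap ceiling, the TSD length
#' scan range, and the assembly size used for genome-proportion reporting
#' (559 Mb). The configuration is echoed into every output header.
#'
#' @slot params named list of parameter values.
#' @export
setClass("HineConfig", representation(params = "list"))

setValidity("HineConfig", function(object) {
  p <- object@params
  msg <- character()
  need <- names(.HINE_DEFAULTS)
  miss <- setdiff(need, names(p))
  if (length(miss)) msg <- c(msg, paste("missing parameters:",
                                        paste(miss, collapse = ", ")))
  chk <- function(cond, m) if (isTRUE(all(cond))) character() else m
  if (!length(miss)) {
    msg <- c(msg,
      chk(p$tr_match > 0 && p$tr_mismatch <= 0 && p$tr_indel <= 0,
          "tandem weights must be match>0, mismatch<=0, indel<=0"),
      chk(p$period_min >= 1 && p$period_min < p$period_max,
          "invalid period range"),
      chk(p$min_copies >= 1, "min_copies must be >= 1"),
      chk(p$redundancy_overlap > 0 && p$redundancy_overlap <= 1,
          "redundancy_overlap must be in (0,1]"),
      chk(p$cluster_identity > 0 && p$cluster_identity <= 1,
          "cluster_identity must be in (0,1]"),
      chk(p$flank_len > 0, "flank_len must be positive"),
      chk(p$empty_min_identity > 0 && p$empty_min_identity <= 1 &&
          p$empty_min_coverage > 0 && p$empty_min_coverage <= 1,
          "empty-site thresholds must be fractions"),
      chk(diff(p$subtir_len_range) >= 0 && diff(p$ir_len_range) >= 0 &&
          diff(p$ir_spacer_range) >= 0 && diff(p$ms_unit_range) >= 0 &&
          diff(p$linker_range) >= 0 && diff(p$tsd_len_range) >= 0,
          "range parameters must be increasing pairs"),
      chk(p$genome_size_for_proportion > 0, "genome size must be positive"))
  }
  if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param ... parameter overrides by name, e.g.
#'   \code{hineConfig(tr_min_score = 60)}. Unknown names are an error.
#' @return a \linkS4class{HineConfig} object.
#' @examples
#' cfg <- hineConfig()
#' cfg$period_min
#' @export
hineConfig <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration overrides must be named")
  unknown <- setdiff(names(over), names(.HINE_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration parameter(s): ",
         paste(unknown, collapse = ", "))
  p <- .HINE_DEFAULTS
  p[names(over)] <- over
  methods::new("HineConfig", params = p)
}

#' @describeIn HineConfig parameter access by name.
#' @param x a \code{HineConfig}.
#' @param name parameter name.
#' @export
setMethod("$", "HineConfig", function(x, name) x@params[[name]])

#' Configuration as a plain list
#' @param cfg a \linkS4class{HineConfig}.
#' @return named list of parameters.
#' @export
configAsList <- function(cfg) {
  stopifnot(methods::is(cfg, "HineConfig"))
  cfg@params
}

setMethod("show", "HineConfig", function(object) {
  p <- object@params
  cat("HineConfig with", length(p), "parameters\n")
  cat("  tandem: weights (", p$tr_match, ",", p$tr_mismatch, ",",
      p$tr_indel, "), min score", p$tr_min_score, ", period [",
      p$period_min, ",", p$period_max, "] bp, >=", p$min_copies, "copies\n")
  cat("  clustering: identity >=", p$cluster_identity,
      "; redundancy overlap >", p$redundancy_overlap, "\n")
  cat("  flanks: up to", p$flank_len, "bp, support >", p$flank_support,
      ", identity >", p$flank_identity, ", RF window", p$rf_window, "bp\n")
  cat("  inverted repeats: weights (", p$ir_match, ",", p$ir_mismatch, ",",
      p$ir_indel, "), min score", p$ir_min_score, ", identity >=",
      p$ir_identity, "\n")
  cat("  empty site: identity >=", p$empty_min_identity, "over coverage >=",
      p$empty_min_coverage, "\n")
  invisible(object)
})

#' Write / read a configuration as YAML
#'
#' The YAML snapshot is mirrored into every pipeline output directory so any
#' result can be traced back to the exact thresholds that produced it.
#'
#' @param cfg a \linkS4class{HineConfig}.
#' @param path file path.
#' @return \code{writeConfigYaml} returns \code{path} invisibly;
#'   \code{readConfigYaml} returns a \linkS4class{HineConfig}.
#' @export
writeConfigYaml <- function(cfg, path) {
  stopifnot(methods::is(cfg, "HineConfig"))
  yaml::write_yaml(cfg@params, path)
  invisible(path)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(path) {
  p <- yaml::read_yaml(path)
  do.call(hineConfig, p)
}
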