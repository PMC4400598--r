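# Fertility summaries: litters and litter size per mating pair, by group.

#' Summarise fertility records by group
#'
#' Records hold one row per mating pair: the number of litters produced over
#' the assay period and the pair's mean litter size (offspring per litter).
#' Each group is summarised as mean +/- s.d. and compared with the designated
#' control group by a two-tailed Welch t-test, separately for litter count and
#' litter size.
#'
#' @param records data frame with columns `group`, `pair_id`, `litters`,
#'   `litter_size`.
#' @param control label of the control group.
#' @return Data frame, one row per group: `group, n_pairs, mean_litters,
#'   sd_litters, mean_litter_size, sd_litter_size, p_litters_vs_control,
#'   p_size_vs_control` (NA for the control itself).
#' @export
summarize_fertility <- function(records, control) {
  need <- c("group", "pair_id", "litters", "litter_size")
  if (!all(need %in% names(records))) {
    validation_error(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  }
  if (!control %in% records$group) {
    validation_error(sprintf("control group '%s' not present", control))
  }
  groups <- unique(records$group)
  counts <- table(records$group)
  if (any(counts < 2L)) {
    validation_error(sprintf(
      "group(s) %s have < 2 mating pairs; SD undefined",
      paste(names(counts)[counts < 2L], collapse = ", ")
    ))
  }
  ctrl <- records[records$group == control, ]
  out <- lapply(groups, function(g) {
    gg <- records[records$group == g, ]
    p_lit <- p_sz <- NA_real_
    if (g != control) {
      p_lit <- t.test(gg$litters, ctrl$litters, var.equal = FALSE)$p.value
      p_sz <- t.test(gg$litter_size, ctrl$litter_size, var.equal = FALSE)$p.value
    }
    data.frame(
      group = g, n_pairs = nrow(gg),
      mean_litters = mean(gg$litters), sd_litters = sd(gg$litters),
      mean_litter_size = mean(gg$litter_size), sd_litter_size = sd(gg$litter_size),
      p_litters_vs_control = p_lit, p_size_vs_control = p_sz,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
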