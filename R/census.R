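# Follicle census: Pedersen-Peters stage classification and one-in-five
# serial-section counting.

FOLLICLE_STAGES <- c("primordial", "primary", "secondary", "antral", "preovulatory")
GC_MORPHOLOGIES <- c("flattened", "cuboidal", "mixed")
ANTRAL_STATES <- c("none", "multiple_small", "single_large")

#' Classify a follicle observation into a maturation stage
#'
#' Operationalises the Pedersen & Peters type-to-stage mapping (types 1-3
#' primordial, 4-5 primary, 6 secondary, 7 antral, 8 preovulatory) through
#' morphological features, since the original types have no numeric criteria:
#' primordial = one flattened granulosa layer; primary = one cuboidal/mixed
#' layer; secondary = multilayered, no antrum; antral = multiple small antral
#' cavities; preovulatory = single large antrum. The feature convention is
#' isolated here so alternative criteria can be swapped in.
#'
#' @param layer_count granulosa layer count (>= 1).
#' @param gc_morphology `"flattened"`, `"cuboidal"` or `"mixed"`.
#' @param antral_cavities `"none"`, `"multiple_small"` or `"single_large"`.
#' @param oocyte_diameter oocyte diameter (> 0; recorded, not used as a cutoff).
#' @return One of `"primordial", "primary", "secondary", "antral", "preovulatory"`.
#' @export
classify_follicle <- function(layer_count, gc_morphology, antral_cavities,
                              oocyte_diameter) {
  if (!is.finite(layer_count) || layer_count < 1 || layer_count != round(layer_count)) {
    validation_error("layer_count must be an integer >= 1")
  }
  if (!gc_morphology %in% GC_MORPHOLOGIES) {
    validation_error(sprintf("unknown gc_morphology '%s'", gc_morphology))
  }
  if (!antral_cavities %in% ANTRAL_STATES) {
    validation_error(sprintf("unknown antral_cavities '%s'", antral_cavities))
  }
  if (!is.finite(oocyte_diameter) || oocyte_diameter <= 0) {
    validation_error("oocyte_diameter must be > 0")
  }
  if (layer_count == 1 && antral_cavities != "none") {
    validation_error("contradictory features: a single-layer follicle cannot have antral cavities")
  }
  if (antral_cavities == "single_large") return("preovulatory")
  if (antral_cavities == "multiple_small") return("antral")
  if (layer_count >= 2) return("secondary")
  if (gc_morphology == "flattened") "primordial" else "primary"
}

#' Census of follicle stages over sampled serial sections
#'
#' Keeps the sections selected by the one-in-five (by default) sampling
#' scheme — section indices congruent to `offset` modulo `round(1/sampling_fraction)`
#' — classifies every observation on them and counts stages per ovary. Counts
#' are raw sums over the sampled sections; no stereological (Abercrombie or
#' fractionator) rescaling is applied, so downstream users can rescale via
#' the reported `sampling_fraction`.
#'
#' @param observations data frame with columns `ovary_id, section_index,
#'   follicle_id, layer_count, gc_morphology, antral_cavities,
#'   oocyte_diameter_um`.
#' @param sampling_fraction fraction of sections examined (default 1/5).
#' @param offset residue class of sampled section indices (default 0).
#' @return Data frame, one row per ovary: `ovary_id`, one count column per
#'   stage, `sections_sampled` (distinct sampled section indices seen),
#'   `sampling_fraction`.
#' @export
census_from_sections <- function(observations, sampling_fraction = 1 / 5, offset = 0L) {
  need <- c("ovary_id", "section_index", "follicle_id", "layer_count",
            "gc_morphology", "antral_cavities", "oocyte_diameter_um")
  if (!all(need %in% names(observations))) {
    validation_error(sprintf("census observations must have columns %s",
                             paste(need, collapse = ", ")))
  }
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    validation_error("sampling_fraction must lie in (0, 1]")
  }
  key <- paste(observations$ovary_id, observations$section_index,
               observations$follicle_id, sep = "\r")
  if (anyDuplicated(key)) {
    validation_error("duplicate (ovary, section, follicle) records in census input")
  }
  period <- max(1L, as.integer(round(1 / sampling_fraction)))
  keep <- observations$section_index %% period == offset
  obs <- observations[keep, , drop = FALSE]
  ovaries <- unique(observations$ovary_id)
  if (length(ovaries) == 0L) {
    out <- data.frame(ovary_id = character(), stringsAsFactors = FALSE)
    for (st in FOLLICLE_STAGES) out[[st]] <- integer()
    out$sections_sampled <- integer()
    out$sampling_fraction <- numeric()
    return(out)
  }
  rows <- lapply(ovaries, function(ov) {
    oo <- obs[obs$ovary_id == ov, , drop = FALSE]
    stages <- if (nrow(oo)) {
      vapply(seq_len(nrow(oo)), function(i) {
        classify_follicle(oo$layer_count[i], oo$gc_morphology[i],
                          oo$antral_cavities[i], oo$oocyte_diameter_um[i])
      }, character(1))
    } else {
      character(0)
    }
    cnt <- table(factor(stages, levels = FOLLICLE_STAGES))
    out <- data.frame(ovary_id = ov, stringsAsFactors = FALSE)
    for (st in FOLLICLE_STAGES) out[[st]] <- as.integer(cnt[[st]])
    out$sections_sampled <- length(unique(oo$section_index))
    out$sampling_fraction <- sampling_fraction
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare per-ovary census counts between two groups
#'
#' Per stage: group means and standard deviations, plus a Welch two-sample
#' t-test p-value across groups. Requires at least two ovaries per group.
#'
#' @param census_a,census_b census tables from [census_from_sections()] for
#'   the two groups.
#' @param labels length-2 character vector naming the groups.
#' @param stages stages to compare (default all five).
#' @return Data frame, one row per stage: `stage, mean_1, sd_1, n_1, mean_2,
#'   sd_2, n_2, p_welch`.
#' @export
compare_census <- function(census_a, census_b, labels = c("group_1", "group_2"),
                           stages = FOLLICLE_STAGES) {
  if (nrow(census_a) < 2L || nrow(census_b) < 2L) {
    validation_error("each group needs >= 2 ovaries; SD undefined otherwise")
  }
  rows <- lapply(stages, function(st) {
    a <- census_a[[st]]
    b <- census_b[[st]]
    p <- if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0   # constant data: t-test undefined
    } else {
      t.test(a, b, var.equal = FALSE)$p.value
    }
    data.frame(stage = st,
               mean_1 = mean(a), sd_1 = sd(a), n_1 = length(a),
               mean_2 = mean(b), sd_2 = sd(b), n_2 = length(b),
               p_welch = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  out
}
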