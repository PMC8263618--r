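## Staged rare-variant prioritization for discordantly predicted,
## whole-genome-sequenced patients.

#' Known VTE-associated genes
#'
#' The curated list of venous-thromboembolism susceptibility genes used
#' as the first-tier search space.
#'
#' @return Character vector of gene symbols.
#' @export
vte_gene_list <- function() {
  c("ABO", "ARID4A", "C4BPB", "EIF5A", "F2", "F3", "F5", "F8", "F9",
    "F13A1", "FGG", "GRK5", "MPHOSPH9", "MAST2", "NUGCC", "OSMR",
    "PLAT", "PLCG2", "PLEK1", "PROC", "PROS1", "SCARA5", "SERPINC1",
    "SLC44A2", "STAB2", "STX10", "STXBP5", "THBD", "TSPAN15", "VWF")
}

.functional_classes <- c("stopgain", "stoploss", "frameshift",
                         "nonsynonymous", "splicing")
.known_classes <- c(.functional_classes, "synonymous", "intronic", "other")

#' Staged rare-variant prioritization
#'
#' Tier 1 keeps variants that are (i) likely functional (stop gain/loss,
#' frameshift, non-synonymous or splicing), (ii) in a known VTE gene,
#' (iii) unreported in population repositories or below `af_max`
#' (default 1 per mille), and (iv) carried by at most `max_carriers`
#' sequenced patients (default 1: singletons). Only when Tier 1 is empty
#' is the search widened to all coding genes (Tier 2), which then also
#' requires in-silico deleteriousness support: scaled CADD at least
#' `cadd_min`, or SIFT at most `sift_max` together with PolyPhen at
#' least `polyphen_min`. Output is ordered by tier then decreasing CADD.
#' An unreported population frequency (NA) passes the rarity filter;
#' unknown functional classes raise a warning and are treated as
#' non-functional.
#'
#' @param variants data.frame with columns `chrom, pos, ref, alt, gene,
#'   func_class, pop_af, carrier_count, sift, polyphen, cadd`.
#' @param gene_list first-tier gene symbols (default [vte_gene_list()]).
#' @param af_max population-frequency ceiling.
#' @param max_carriers carrier-count ceiling.
#' @param cadd_min,sift_max,polyphen_min Tier-2 deleteriousness cutoffs.
#' @return The surviving rows with a `tier` column prepended, ordered by
#'   tier then CADD descending (zero rows when nothing survives).
#' @export
prioritize_variants <- function(variants, gene_list = vte_gene_list(),
                                af_max = 0.001, max_carriers = 1,
                                cadd_min = 20, sift_max = 0.05,
                                polyphen_min = 0.85) {
  stopifnot(is.data.frame(variants), af_max > 0, max_carriers >= 0)
  need <- c("gene", "func_class", "pop_af", "carrier_count",
            "sift", "polyphen", "cadd")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols))
    stop("variants table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  unknown <- setdiff(unique(variants$func_class), .known_classes)
  if (length(unknown))
    warning("unknown functional class(es) treated as non-functional: ",
            paste(unknown, collapse = ", "))

  functional <- variants$func_class %in% .functional_classes
  rare <- is.na(variants$pop_af) | variants$pop_af < af_max
  singleton <- variants$carrier_count <= max_carriers
  base <- functional & rare & singleton

  tier1 <- base & variants$gene %in% gene_list
  if (any(tier1)) {
    out <- variants[tier1, , drop = FALSE]
    out <- cbind(tier = 1L, out)
  } else {
    deleterious <- (!is.na(variants$cadd) & variants$cadd >= cadd_min) |
      (!is.na(variants$sift) & variants$sift <= sift_max &
         !is.na(variants$polyphen) & variants$polyphen >= polyphen_min)
    out <- variants[base & deleterious, , drop = FALSE]
    out <- cbind(tier = rep(2L, nrow(out)), out)
  }
  ord <- order(-replace(out$cadd, is.na(out$cadd), -Inf),
               seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write annotated variant tables
#'
#' Plain TSV, one variant per row, columns as in
#' [prioritize_variants()].
#'
#' @param variants data.frame; `path` file path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  v <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene", "func_class", "pop_af", "carrier_count")
  missing_cols <- setdiff(need, names(v))
  if (length(missing_cols))
    stop("malformed variant table ", path, ": missing ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  v
}
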