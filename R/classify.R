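# Mechanistic classification of DBD mutants from (dG_apo, K_Zn, K_DNA).

#' Classify mutants by stability loss and zinc-affinity loss
#'
#' Assigns each variant a mechanistic class from its apo-state stability and
#' native-site zinc affinity relative to the wild type:
#' * `stability`: destabilised by more than `ddg_threshold` kcal/mol with a
#'   K_Zn fold-change at or below `kzn_fold_threshold`;
#' * `zinc_binding`: K_Zn weakened by more than `kzn_fold_threshold`-fold
#'   with stability loss at or below `ddg_threshold`;
#' * `mixed`: both thresholds exceeded;
#' * `dna_contact_candidate`: neither exceeded (a DNA-contact mechanism is
#'   confirmed only by corroborating K_DNA loss, reported separately);
#' * `unclassified`: no usable stability measurement.
#'
#' Comparisons are strict (a variant sitting exactly at a threshold is not
#' impaired). Variants whose K_Zn could not be measured
#' (`k_zn_identifiable = FALSE` or missing `k_zn`) are listed as `stability`
#' when destabilised, with `k_zn_caveat = TRUE` because a mixed mechanism
#' cannot be excluded.
#'
#' @param records Data frame with columns `name`, `dg_apo` (kcal/mol at the
#'   reference temperature), `k_zn` (M; may be NA), and optionally
#'   `k_zn_identifiable` (logical) and K_DNA columns for confirmation:
#'   `k_dna_rel` (median affinity relative to WT, >1 = tighter).
#' @param wt_label Name of the wild-type row (default "WT").
#' @param ddg_threshold Stability-loss threshold, kcal/mol (default 1.0).
#' @param kzn_fold_threshold K_Zn fold-change threshold (default 10).
#' @return The input tibble with `ddg_apo`, `kzn_fold`, `class_label`,
#'   `k_zn_caveat`, and (when K_DNA data are present) `dna_contact_confirmed`.
#' @examples
#' recs <- tibble::tibble(
#'   name = c("WT", "R175H", "V272M"),
#'   dg_apo = c(6.4, 6.2, 4.4),
#'   k_zn = c(7e-15, 3.5e-11, 8.4e-15))
#' classify_mutants(recs)
#' @export
classify_mutants <- function(records, wt_label = "WT", ddg_threshold = 1.0,
                             kzn_fold_threshold = 10.0) {
  need <- c("name", "dg_apo", "k_zn")
  if (!all(need %in% names(records))) {
    abort("`records` needs columns name, dg_apo, k_zn.")
  }
  wt <- records[records$name == wt_label, ]
  if (nrow(wt) != 1 || is.na(wt$dg_apo) || is.na(wt$k_zn)) {
    abort(sprintf("exactly one '%s' row with dg_apo and k_zn is required.",
                  wt_label))
  }
  out <- as_tibble(records)
  if (!"k_zn_identifiable" %in% names(out)) {
    out$k_zn_identifiable <- !is.na(out$k_zn)
  }
  out$k_zn_identifiable[is.na(out$k_zn_identifiable)] <- FALSE
  out$ddg_apo <- wt$dg_apo - out$dg_apo
  out$kzn_fold <- out$k_zn / wt$k_zn
  out$k_zn_caveat <- FALSE
  lab <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (is.na(out$dg_apo[i])) {
      lab[i] <- "unclassified"
      next
    }
    destab <- out$ddg_apo[i] > ddg_threshold
    if (!out$k_zn_identifiable[i] || is.na(out$kzn_fold[i])) {
      if (destab) {
        lab[i] <- "stability"
        out$k_zn_caveat[i] <- TRUE
      } else {
        lab[i] <- "unclassified"
      }
      next
    }
    zn_loss <- out$kzn_fold[i] > kzn_fold_threshold
    lab[i] <- if (destab && zn_loss) "mixed"
      else if (destab) "stability"
      else if (zn_loss) "zinc_binding"
      else "dna_contact_candidate"
  }
  out$class_label <- lab
  if ("k_dna_rel" %in% names(out)) {
    out$dna_contact_confirmed <- out$class_label == "dna_contact_candidate" &
      !is.na(out$k_dna_rel) & out$k_dna_rel < 1 / kzn_fold_threshold
  }
  out
}

#' Summary of a classified mutant panel
#'
#' Counts per class, the fraction of variants with impaired folding
#' thermodynamics (stability, zinc-binding, or mixed), and the scatter
#' coordinates (stability loss vs log10 K_Zn fold-change) used for the
#' class-partition plot.
#'
#' @param records Output of [classify_mutants()].
#' @return List of class `classification_report` with elements `summary`
#'   (class counts), `fraction_impaired`, `n`, and `scatter` (per-variant
#'   coordinates and labels).
#' @export
classification_report <- function(records) {
  if (!"class_label" %in% names(records)) {
    abort("run classify_mutants() first.")
  }
  if (nrow(records) == 0) abort("empty record set.")
  impaired_classes <- c("stability", "zinc_binding", "mixed")
  summary <- dplyr::count(records, .data$class_label, name = "n")
  structure(list(
    summary = summary,
    n = nrow(records),
    fraction_impaired = mean(records$class_label %in% impaired_classes),
    scatter = dplyr::transmute(records, .data$name,
                               ddg_apo = .data$ddg_apo,
                               log10_kzn_fold = log10(.data$kzn_fold),
                               class_label = .data$class_label)),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d variants, %.0f%% impaired\n",
              x$n, 100 * x$fraction_impaired))
  print(x$summary)
  invisible(x)
}
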