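#' Canonical 35-channel montage order
#'
#' The fixed channel order used for connectivity images: 32 EEG channels
#' followed by the 3 ECG leads (EXG1 upper-right chest, EXG2 upper-left
#' chest, EXG3 left abdomen). Axis position in every rendered image follows
#' this order.
#'
#' @return character vector of 35 labels.
#' @export
canonical_montage <- function() {
  c("PO3", "O1", "C4", "F7", "FC5", "FC1", "Fp1", "CP1", "FC2", "Pz",
    "Fp2", "AF4", "Cz", "T8", "CP6", "AF3", "P3", "P7", "Oz", "F8",
    "CP5", "FC6", "F3", "C3", "Fz", "F4", "CP2", "P4", "P8", "PO4",
    "O2", "T7", "EXG1", "EXG2", "EXG3")
}

#' Reorder a connectivity matrix to a canonical channel order
#'
#' Simultaneously permutes rows and columns so the labels match `canonical`;
#' ECG channels end up in the trailing positions of the canonical montage.
#'
#' @param cm a `connectivity_matrix`.
#' @param canonical target label order; must be a permutation of the matrix's
#'   labels.
#' @return the reordered `connectivity_matrix`.
#' @export
order_channels <- function(cm, canonical = canonical_montage()) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  missing_ <- setdiff(canonical, cm$labels)
  extra <- setdiff(cm$labels, canonical)
  if (length(missing_) || length(extra))
    stop("label mismatch; missing: [", paste(missing_, collapse = ", "),
         "], extra: [", paste(extra, collapse = ", "), "]")
  perm <- match(canonical, cm$labels)
  cm$values <- cm$values[perm, perm, drop = FALSE]
  cm$kinds <- cm$kinds[perm]
  cm$labels <- canonical
  dimnames(cm$values) <- list(target = canonical, source = canonical)
  cm
}
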