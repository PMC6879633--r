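#' Major/minor state chemical shift pair
#'
#' Amide (or indole NH) chemical shifts of the major state peak and, when
#' observed, the linked minor state peak of one residue.
#'
#' @param residue_label residue identifier
#' @param dH_major,dN_major major-state 1H and 15N shifts (ppm)
#' @param dH_minor,dN_minor minor-state shifts (ppm); omit when no minor
#'   peak is observed
#' @return an object of class `shift_pair`
#' @export
shift_pair <- function(residue_label, dH_major, dN_major,
                       dH_minor = NULL, dN_minor = NULL) {
  has_minor <- !is.null(dH_minor) && !is.null(dN_minor) &&
    !is.na(dH_minor) && !is.na(dN_minor)
  vals <- c(dH_major, dN_major,
            if (has_minor) c(dH_minor, dN_minor))
  if (any(!is.finite(vals))) stop("chemical shifts must be finite")
  structure(list(residue_label = residue_label,
                 dH_major = dH_major, dN_major = dN_major,
                 dH_minor = if (has_minor) dH_minor else NULL,
                 dN_minor = if (has_minor) dN_minor else NULL,
                 has_minor = has_minor),
            class = "shift_pair")
}

#' Combined amide chemical-shift displacement
#'
#' Weighted two-nucleus displacement between major and minor state peaks:
#' delta = sqrt(dH^2 + (dN/5)^2), the conventional combined 1H/15N metric
#' with the nitrogen difference scaled by 5.
#'
#' @param pair a [shift_pair] with an observed minor state
#' @return displacement in ppm (nonnegative scalar)
#' @export
compute_delta_delta <- function(pair) {
  stopifnot(inherits(pair, "shift_pair"))
  if (!pair$has_minor) stop("minor state not observed; displacement undefined")
  dH <- pair$dH_major - pair$dH_minor
  dN <- pair$dN_major - pair$dN_minor
  sqrt(dH^2 + (dN / 5)^2)
}

#' Classify a variant's exchange mode from its shift displacement
#'
#' Variants with no minor-state peaks show no exchange. Among variants
#' with linked minor peaks, a small displacement is characteristic of
#' monomer-dimer exchange (the dimer interface is remote from the tryptophan
#' probe, so dimerization perturbs its shifts only weakly), while a large
#' displacement indicates a genuine side-chain conformational change
#' between core-buried and solvent-exposed states. The default threshold
#' of 0.6 ppm sits in the gap between the two empirically observed
#' clusters (about 0.32-0.34 ppm vs 0.94-1.32 ppm).
#'
#' @param pair a [shift_pair]
#' @param threshold classification threshold (ppm), > 0
#' @return an object of class `exchange_mode_call` with `delta_delta`
#'   (`NA` when no minor state) and `mode`
#' @export
classify_mode <- function(pair, threshold = 0.6) {
  stopifnot(inherits(pair, "shift_pair"))
  if (threshold <= 0) stop("threshold must be positive")
  if (!pair$has_minor) {
    dd <- NA_real_
    mode <- "no exchange"
  } else {
    dd <- compute_delta_delta(pair)
    mode <- if (dd < threshold) "monomer-dimer exchange"
    else "Trp43 conformational exchange"
  }
  structure(list(residue_label = pair$residue_label,
                 delta_delta = dd, mode = mode, threshold = threshold),
            class = "exchange_mode_call")
}

#' @export
print.exchange_mode_call <- function(x, ...) {
  cat(sprintf("%s: %s (delta-delta = %s ppm)\n", x$residue_label, x$mode,
              if (is.na(x$delta_delta)) "n/a" else sprintf("%.3g", x$delta_delta)))
  invisible(x)
}

#' Read shift pairs from TSV
#'
#' Columns: residue, dH_major, dN_major, dH_minor, dN_minor; the minor
#' columns may be empty (NA) for residues without observed minor peaks.
#'
#' @param file path to a tab-separated file
#' @return a list of [shift_pair]
#' @export
read_shifts_tsv <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  d <- utils::read.delim(file, check.names = FALSE)
  need <- c("residue", "dH_major", "dN_major")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(d)), function(i) {
    shift_pair(residue_label = as.character(d$residue[i]),
               dH_major = d$dH_major[i], dN_major = d$dN_major[i],
               dH_minor = if ("dH_minor" %in% names(d)) d$dH_minor[i] else NULL,
               dN_minor = if ("dN_minor" %in% names(d)) d$dN_minor[i] else NULL)
  })
}
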