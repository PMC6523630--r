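# Spectrum data model, peak alignment and dot-product similarity.

#' Construct a spectrum
#'
#' A spectrum is a peak table (m/z, relative intensity in \[0, 100\],
#' optional annotation) sorted ascending by m/z, plus free-form metadata
#' (compound name/id, precursor m/z, adduct, collision energy, provenance).
#' Duplicate m/z values within 1e-6 are rejected.
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param intensity Relative intensities in \[0, 100\].
#' @param annotation Optional character vector of peak annotations.
#' @param metadata Named list of metadata.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(mz, intensity, annotation = NULL, metadata = list()) {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity))
  if (length(mz)) {
    if (any(mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
    if (any(intensity < 0 | intensity > 100)) {
      stop("peak intensity must be in [0, 100]", call. = FALSE)
    }
  }
  if (is.null(annotation)) annotation <- rep("", length(mz))
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]; annotation <- annotation[ord]
  if (length(mz) > 1 && any(diff(mz) < 1e-6)) {
    stop("duplicate peak m/z within 1e-6", call. = FALSE)
  }
  peaks <- data.frame(mz = mz, intensity = intensity,
                      annotation = annotation, stringsAsFactors = FALSE)
  structure(list(peaks = peaks, metadata = metadata), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  md <- x$metadata
  cat("<spectrum> ", nrow(x$peaks), " peaks",
      if (!is.null(md$name)) paste0(" | ", md$name),
      if (!is.null(md$adduct)) paste0(" ", md$adduct),
      if (!is.null(md$energy)) paste0(" @ ", md$energy, " eV"),
      "\n", sep = "")
  print(utils::head(x$peaks, 12))
  invisible(x)
}

n_peaks <- function(s) nrow(s$peaks)

#' Base-peak normalize a spectrum
#'
#' Scales intensities so that the most intense peak is 100. Idempotent;
#' order-preserving. An empty spectrum is an error.
#'
#' @param s A `spectrum`.
#' @return The normalized `spectrum`.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (!n_peaks(s)) stop("cannot normalize an empty spectrum", call. = FALSE)
  top <- max(s$peaks$intensity)
  if (top <= 0) stop("cannot normalize a zero-intensity spectrum",
                     call. = FALSE)
  s$peaks$intensity <- s$peaks$intensity * (100 / top)
  s
}

#' Align peaks of two spectra within an m/z tolerance
#'
#' Greedy one-to-one matching: all cross pairs within `tol` are ranked by
#' ascending absolute m/z difference (ties broken by the lower m/z of the
#' second spectrum's peak, then of the first's) and accepted in that order,
#' skipping peaks already matched. Deterministic.
#'
#' @param a,b `spectrum` objects.
#' @param tol Non-negative m/z tolerance in Da.
#' @return List with `pairs` (data.frame: `ia`, `ib`, `mz_a`, `mz_b`,
#'   `delta`), `unmatched_a`, `unmatched_b` (peak indices).
#' @export
align_peaks <- function(a, b, tol) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (!is.numeric(tol) || tol < 0) {
    stop("alignment tolerance must be >= 0", call. = FALSE)
  }
  mza <- a$peaks$mz; mzb <- b$peaks$mz
  if (!length(mza) || !length(mzb)) {
    return(list(pairs = data.frame(ia = integer(0), ib = integer(0),
                                   mz_a = numeric(0), mz_b = numeric(0),
                                   delta = numeric(0)),
                unmatched_a = seq_along(mza), unmatched_b = seq_along(mzb)))
  }
  cand <- expand.grid(ia = seq_along(mza), ib = seq_along(mzb))
  cand$delta <- abs(mza[cand$ia] - mzb[cand$ib])
  cand <- cand[cand$delta <= tol + 1e-12, , drop = FALSE]
  cand <- cand[order(cand$delta, mzb[cand$ib], mza[cand$ia]), , drop = FALSE]
  used_a <- logical(length(mza)); used_b <- logical(length(mzb))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$ia[k]; j <- cand$ib[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$ia), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = data.frame(ia = pairs$ia, ib = pairs$ib,
                          mz_a = mza[pairs$ia], mz_b = mzb[pairs$ib],
                          delta = pairs$delta),
       unmatched_a = which(!used_a), unmatched_b = which(!used_b))
}

#' Dot-product (cosine) spectral similarity
#'
#' Both spectra are base-peak normalized, aligned within `tol`, and paired
#' intensity vectors are built over the union of peaks (an unmatched peak
#' contributes intensity 0 on the other side). The score is the cosine
#' `sum(u*v) / (||u|| * ||v||)`, in \[0, 1\], symmetric, and invariant to
#' intensity rescaling of either spectrum.
#'
#' @param a,b Non-empty `spectrum` objects.
#' @param tol Alignment tolerance in Da (see [align_peaks()]). Defaults to
#'   0.01 Da, appropriate when both spectra are predicted; use ~0.25 Da when
#'   either side is experimental.
#' @return Similarity score in \[0, 1\].
#' @export
dot_product_similarity <- function(a, b, tol = 0.01) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (!n_peaks(a) || !n_peaks(b)) {
    stop("dot_product_similarity requires non-empty spectra", call. = FALSE)
  }
  a <- normalize_spectrum(a); b <- normalize_spectrum(b)
  al <- align_peaks(a, b, tol)
  ia <- al$pairs$ia; ib <- al$pairs$ib
  u <- c(a$peaks$intensity[ia], a$peaks$intensity[al$unmatched_a],
         rep(0, length(al$unmatched_b)))
  v <- c(b$peaks$intensity[ib], rep(0, length(al$unmatched_a)),
         b$peaks$intensity[al$unmatched_b])
  denom <- sqrt(sum(u^2)) * sqrt(sum(v^2))
  if (denom == 0) return(0)
  min(1, sum(u * v) / denom)
}
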