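# Congener profile normalization and similarity.

#' Normalize a congener distribution to mass fractions
#'
#' @param values Named nonnegative numeric vector (one element per peak).
#' @param label Optional profile label.
#' @return A `profile`: named numeric vector of fractions summing to 1, with
#'   attribute `label`.
#' @examples
#' normalize_profile(c(PCB4 = 2, PCB8 = 2, PCB11 = 4))
#' @export
normalize_profile <- function(values, label = "profile") {
  v <- as.numeric(values)
  if (any(!is.finite(v)) || any(v < 0)) stop("profile values must be nonnegative")
  s <- sum(v)
  if (s <= 0) stop("all-zero profile cannot be normalized")
  out <- stats::setNames(v / s, names(values))
  attr(out, "label") <- label
  class(out) <- "profile"
  out
}

#' @export
print.profile <- function(x, ...) {
  cat("<profile>", attr(x, "label"), "-", length(x), "peaks; top:\n")
  print(utils::head(sort(unclass(x), decreasing = TRUE), 5))
  invisible(x)
}

#' Cosine similarity between two congener profiles
#'
#' `cos(theta) = <a, b> / (|a| |b|)`: 1 for identical shapes, 0 for profiles
#' with disjoint support. If the peak sets differ, the profiles are
#' intersected and renormalized with a warning.
#'
#' @param a,b `profile` objects or named nonnegative vectors.
#' @return Cosine similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0L) stop("profiles share no peaks")
    warning("profiles on different peak sets; intersecting ",
            length(common), " shared peaks and renormalizing")
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("profiles must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm profile")
  min(1, max(0, sum(a * b) / (na * nb)))
}

#' Pairwise profile similarity report
#'
#' Computes the full pairwise cosine-similarity matrix among sample profiles
#' and, optionally, against reference profiles (e.g. Aroclor mixtures).
#'
#' @param samples Named list of `profile` objects (>= 2).
#' @param references Optional named list of reference `profile` objects.
#' @return A list with `matrix` (samples x samples), `within_mean`,
#'   `within_sd` (off-diagonal pairwise summary), and, when references are
#'   given, `reference_matrix` (samples x references), `reference_summary`
#'   (mean +- sd per reference), and `best_reference` per sample.
#' @export
profile_similarity_report <- function(samples, references = NULL) {
  if (length(samples) < 2L) stop("need at least 2 sample profiles")
  ns <- length(samples)
  labs <- names(samples)
  if (is.null(labs)) labs <- paste0("sample", seq_len(ns))
  m <- matrix(1, ns, ns, dimnames = list(labs, labs))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      m[i, j] <- m[j, i] <- cosine_similarity(samples[[i]], samples[[j]])
    }
  }
  off <- m[lower.tri(m)]
  out <- list(matrix = m, within_mean = mean(off),
              within_sd = if (length(off) > 1L) stats::sd(off) else 0)
  if (!is.null(references) && length(references) > 0L) {
    rl <- names(references)
    rm <- matrix(NA_real_, ns, length(references), dimnames = list(labs, rl))
    for (i in seq_len(ns)) {
      for (j in seq_along(references)) {
        rm[i, j] <- cosine_similarity(samples[[i]], references[[j]])
      }
    }
    out$reference_matrix <- rm
    out$reference_summary <- data.frame(
      reference = rl,
      mean = colMeans(rm),
      sd = apply(rm, 2, stats::sd),
      row.names = NULL
    )
    out$best_reference <- rl[max.col(rm)]
  }
  out
}
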