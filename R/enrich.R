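## Regional enrichment of chromosome-mapped spacers: unique-spacer counts
## in equal-width windows (origin, terminus, CRISPR locus) on the circular
## chromosome, normalized to the count in a reference window. Counting is
## by spacer start position; windows must be disjoint so a spacer counts in
## at most one named region.

#' Define equal-width regions on a circular chromosome
#'
#' Builds a region set from window centres: each named window spans
#' `window_width` bases centred on its declared position (wrapping across
#' the circular origin is allowed and handled by splitting the interval),
#' plus a mandatory reference window `Ref` starting at `ref_start`
#' (default the region spanning coordinates 0 to `window_width`).
#'
#' @param chromosome_length circular chromosome length in bp.
#' @param centers named numeric vector of window centre positions, e.g.
#'   `c(Ori = 3925744, Ter = 1588774, Cr = 2885000)`.
#' @param window_width window width in bp (default 670000).
#' @param ref_start start of the reference window (default 0).
#' @return object of class `region_set`: list with `intervals` (data frame
#'   `name`, `start`, `end`; 0-based half-open, non-wrapping),
#'   `chromosome_length` and `window_width`.
#' @export
region_set <- function(chromosome_length,
                       centers = c(Ori = 3925744, Ter = 1588774,
                                   Cr = 2885000),
                       window_width = 670000, ref_start = 0) {
  W <- as.integer(window_width)
  starts <- as.integer(round(centers - W / 2))
  df <- data.frame(name = c("Ref", names(centers)),
                   start = c(as.integer(ref_start), starts),
                   end = c(as.integer(ref_start) + W, starts + W),
                   stringsAsFactors = FALSE)
  region_set_from_intervals(df, chromosome_length, W)
}

#' Build a region set from explicit intervals
#'
#' @param intervals data frame with columns `name`, `start`, `end`
#'   (0-based half-open on the circular chromosome; `end` may exceed the
#'   chromosome length or `start` may be negative to express wrapping).
#' @param chromosome_length circular chromosome length in bp.
#' @param window_width required total span of every named region.
#' @return a `region_set` object.
#' @export
region_set_from_intervals <- function(intervals, chromosome_length,
                                      window_width = 670000) {
  L <- as.integer(chromosome_length)
  W <- as.integer(window_width)
  stopifnot(L > 0L, W > 0L, W <= L,
            all(c("name", "start", "end") %in% names(intervals)))
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    s <- ((intervals$start[i]) %% L)
    len <- intervals$end[i] - intervals$start[i]
    stopifnot(len > 0L, len <= L)
    e <- s + len
    if (e <= L) {
      out[[length(out) + 1L]] <- data.frame(name = intervals$name[i],
                                            start = s, end = e)
    } else {                                  # wraps the circular origin
      out[[length(out) + 1L]] <- data.frame(name = intervals$name[i],
                                            start = s, end = L)
      out[[length(out) + 1L]] <- data.frame(name = intervals$name[i],
                                            start = 0L, end = e - L)
    }
  }
  iv <- do.call(rbind, out)
  iv$start <- as.integer(iv$start)
  iv$end <- as.integer(iv$end)
  if (!"Ref" %in% iv$name)
    stop("a reference region named 'Ref' is mandatory")
  span <- tapply(iv$end - iv$start, iv$name, sum)
  bad <- names(span)[span != W]
  if (length(bad))
    stop("total span of region(s) ", paste(bad, collapse = ", "),
         " differs from window_width (", W, " bp)")
  o <- order(iv$start)
  if (any(iv$start[o][-1L] < iv$end[o][-nrow(iv)]))
    stop("named regions overlap; region definitions must be disjoint")
  structure(list(intervals = iv[o, , drop = FALSE],
                 chromosome_length = L, window_width = W),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("Region set on a %d bp circular chromosome (windows %d bp)\n",
              x$chromosome_length, x$window_width))
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Count unique spacers per region
#'
#' A spacer is counted in a region when its start position falls in any of
#' the region's intervals (modulo circularity). Counting is by start
#' position, not overlap, so window edges never double count.
#'
#' @param mapped a `mapping_results` data frame (only uniquely
#'   chromosome-mapped spacers are used), or an integer vector of 0-based
#'   positions.
#' @param regions a [region_set()].
#' @return named integer vector of per-region counts, with attribute
#'   `total` (number of chromosome-mapped spacers considered).
#' @export
count_in_regions <- function(mapped, regions) {
  stopifnot(inherits(regions, "region_set"))
  if (is.data.frame(mapped)) {
    mapped <- mapped[mapped$target == "chromosome", , drop = FALSE]
    pos <- mapped$position
  } else {
    pos <- mapped
  }
  pos <- as.integer(pos) %% regions$chromosome_length
  iv <- regions$intervals
  counts <- setNames(integer(length(unique(iv$name))), unique(iv$name))
  for (i in seq_len(nrow(iv)))
    counts[iv$name[i]] <- counts[iv$name[i]] +
      sum(pos >= iv$start[i] & pos < iv$end[i])
  attr(counts, "total") <- length(pos)
  counts
}

#' Relative spacer quantities per region
#'
#' Each region's relative quantity is its unique-spacer count divided by
#' the reference-window count. The 95% confidence interval of the ratio is
#' obtained from the exact (Clopper-Pearson) binomial interval of the
#' conditional proportion k_region / (k_region + k_ref), transformed to the
#' odds scale.
#'
#' @param counts named per-region counts from [count_in_regions()].
#' @param ref name of the reference region (default `"Ref"`).
#' @return data frame of class `enrichment_table` with columns `region`,
#'   `count`, `relative`, `ci_lo`, `ci_hi`. The reference region's
#'   relative quantity is exactly 1.
#' @export
relative_quantities <- function(counts, ref = "Ref") {
  stopifnot(ref %in% names(counts))
  kr <- counts[[ref]]
  if (kr == 0L)
    stop("reference window contains zero spacers; supply more data or ",
         "choose a different reference window")
  regions <- names(counts)
  rel <- numeric(length(regions))
  lo <- hi <- rep(NA_real_, length(regions))
  for (i in seq_along(regions)) {
    k <- counts[[regions[i]]]
    if (regions[i] == ref) {
      rel[i] <- 1
      next
    }
    rel[i] <- k / kr
    ci <- stats::binom.test(k, k + kr)$conf.int
    lo[i] <- ci[1L] / (1 - ci[1L])
    hi[i] <- if (ci[2L] >= 1) Inf else ci[2L] / (1 - ci[2L])
  }
  out <- data.frame(region = regions, count = as.integer(counts),
                    relative = rel, ci_lo = lo, ci_hi = hi,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Regional enrichment of chromosome-mapped spacers
#'
#' Convenience wrapper: [count_in_regions()] followed by
#' [relative_quantities()].
#'
#' @inheritParams count_in_regions
#' @inheritParams relative_quantities
#' @return an `enrichment_table`.
#' @export
enrichment <- function(mapped, regions, ref = "Ref") {
  relative_quantities(count_in_regions(mapped, regions), ref = ref)
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Relative spacer quantities (normalized to the reference window)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bar plot of regional enrichment
#'
#' @param x an `enrichment_table`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.enrichment_table <- function(x, ...) {
  bp <- graphics::barplot(x$relative, names.arg = x$region,
                          ylab = "relative spacer quantity",
                          ylim = c(0, max(x$ci_hi[is.finite(x$ci_hi)],
                                          x$relative, 1, na.rm = TRUE) * 1.1),
                          ...)
  ok <- is.finite(x$ci_lo) & is.finite(x$ci_hi)
  if (any(ok))
    graphics::arrows(bp[ok], x$ci_lo[ok], bp[ok], x$ci_hi[ok],
                     angle = 90, code = 3, length = 0.05)
  graphics::abline(h = 1, lty = 2)
  invisible(bp)
}
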