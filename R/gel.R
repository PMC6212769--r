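## Densitometry-based quantification of spacer acquisition. A gel lane
## carries the intensities of the unexpanded (C) and expanded (C+1) array
## bands; percent acquisition is 100 * C1 / (C1 + C), and background from
## the empty-vector (pBad) control of the same strain and passage is
## subtracted, floored at zero.

validate_gel_lanes <- function(lanes) {
  need <- c("strain", "plasmid", "passage", "intensity_C", "intensity_C1")
  miss <- setdiff(need, names(lanes))
  if (length(miss))
    stop("gel lane table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(lanes$intensity_C < 0) || any(lanes$intensity_C1 < 0))
    stop("band intensities must be >= 0")
  lanes
}

#' Percent spacer acquisition from band intensities
#'
#' Percentage of expanded arrays in a lane:
#' `100 * C1 / (C1 + C)`, where `C` is the unexpanded-band and `C1` the
#' expanded-band intensity. Scale-invariant in the two intensities.
#'
#' @param intensity_C unexpanded (parental) band intensity, arbitrary units.
#' @param intensity_C1 expanded band intensity, arbitrary units.
#' @return percent acquisition in `[0, 100]` (vectorized).
#' @export
percent_acquisition <- function(intensity_C, intensity_C1) {
  stopifnot(all(intensity_C >= 0), all(intensity_C1 >= 0))
  tot <- intensity_C + intensity_C1
  if (any(tot == 0))
    stop("both band intensities are zero: lane is unquantifiable")
  100 * intensity_C1 / tot
}

#' Empty-vector background subtraction
#'
#' Subtracts the empty-vector (pBad) control percentage from the test
#' (pCas1-2) percentage of the same strain and passage, flooring the
#' result at zero (a negative percentage of expanded arrays is not
#' meaningful).
#'
#' @param test percent acquisition with the Cas1-Cas2 plasmid.
#' @param control percent acquisition with the empty vector.
#' @param strain_test,strain_control,passage_test,passage_control optional
#'   labels; when given, mismatched strain or passage labels raise an
#'   error (controls must come from the same strain and passage).
#' @return corrected percent acquisition (vectorized).
#' @export
background_correct <- function(test, control,
                               strain_test = NULL, strain_control = NULL,
                               passage_test = NULL, passage_control = NULL) {
  if (!is.null(strain_test) && !is.null(strain_control) &&
      any(strain_test != strain_control))
    stop("test and control lanes come from different strains")
  if (!is.null(passage_test) && !is.null(passage_control) &&
      any(passage_test != passage_control))
    stop("test and control lanes come from different passages")
  pmax(test - control, 0)
}

#' Quantify spacer acquisition across gel lanes
#'
#' Pairs each test lane (Cas1-Cas2 plasmid) with the empty-vector control
#' lane of the same strain and passage and computes raw and
#' background-corrected percent acquisition. Subtraction is applied to
#' percentages by default; `on = "intensity"` instead subtracts the
#' control band intensities before computing the percentage.
#'
#' @param lanes gel lane data frame (see [read_gel_tsv()]) with columns
#'   `strain`, `plasmid`, `passage`, `intensity_C`, `intensity_C1`.
#' @param test_plasmid,control_plasmid plasmid labels identifying test and
#'   control lanes (defaults `"pCas1-2"` and `"pBad"`).
#' @param on subtract on `"percent"` (default) or `"intensity"`.
#' @return data frame with columns `strain`, `passage`,
#'   `percent_raw` and `percent_corrected`. Test lanes without a matching
#'   control keep `percent_corrected = percent_raw` (no background
#'   available) and are flagged in the `has_control` column.
#' @export
quantify_adaptation <- function(lanes, test_plasmid = "pCas1-2",
                                control_plasmid = "pBad",
                                on = c("percent", "intensity")) {
  on <- match.arg(on)
  lanes <- validate_gel_lanes(lanes)
  test <- lanes[lanes$plasmid == test_plasmid, , drop = FALSE]
  ctrl <- lanes[lanes$plasmid == control_plasmid, , drop = FALSE]
  if (nrow(test) == 0L)
    stop("no lanes with test plasmid '", test_plasmid, "'")
  key <- function(d) paste(d$strain, d$passage, sep = "\r")
  ctrl_idx <- match(key(test), key(ctrl))
  raw <- percent_acquisition(test$intensity_C, test$intensity_C1)
  corrected <- raw
  has_control <- !is.na(ctrl_idx)
  if (any(has_control)) {
    ci <- ctrl_idx[has_control]
    if (on == "percent") {
      ctrl_pct <- percent_acquisition(ctrl$intensity_C[ci],
                                      ctrl$intensity_C1[ci])
      corrected[has_control] <- background_correct(raw[has_control], ctrl_pct)
    } else {
      c1 <- pmax(test$intensity_C1[has_control] - ctrl$intensity_C1[ci], 0)
      c0 <- pmax(test$intensity_C[has_control] - ctrl$intensity_C[ci], 0)
      corrected[has_control] <- ifelse(c0 + c1 > 0, 100 * c1 / (c0 + c1), 0)
    }
  }
  data.frame(strain = test$strain, passage = test$passage,
             percent_raw = raw, percent_corrected = corrected,
             has_control = has_control, stringsAsFactors = FALSE)
}

#' Summarize replicate acquisition measurements
#'
#' Mean, minimum, maximum and replicate count per strain and passage.
#' Groups with a single replicate are flagged (the assay expects at least
#' two independent experiments per strain).
#'
#' @param measurements data frame from [quantify_adaptation()] (uses the
#'   `percent_corrected` column, falling back to `percent_raw`).
#' @param value column to summarize.
#' @return data frame with columns `strain`, `passage`, `mean`, `min`,
#'   `max`, `n`, `single_replicate`.
#' @export
summarize_replicates <- function(measurements,
                                 value = c("percent_corrected",
                                           "percent_raw")) {
  value <- match.arg(value)
  if (!value %in% names(measurements)) value <- "percent_raw"
  v <- measurements[[value]]
  g <- interaction(measurements$strain, measurements$passage, drop = TRUE)
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    i <- g == lev
    data.frame(strain = measurements$strain[i][1L],
               passage = measurements$passage[i][1L],
               mean = mean(v[i]), min = min(v[i]), max = max(v[i]),
               n = sum(i), stringsAsFactors = FALSE)
  }))
  out$single_replicate <- out$n == 1L
  out <- out[order(out$strain, out$passage), , drop = FALSE]
  rownames(out) <- NULL
  out
}
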