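#' Count guanosines in an RNA species body
#'
#' With body-labeling by [alpha-32P]GTP every templated G carries label, so a
#' band's intensity is proportional to molar amount times G count. The cap G
#' contributed by the unlabeled GpppG dinucleotide is not part of the body
#' and is not counted.
#'
#' @param sequence RNA sequence (character or [Biostrings::RNAString]).
#' @return integer G count.
#' @examples
#' gCount("GGAUG")  # 3
#' @export
gCount <- function(sequence) {
  s <- asRnaChar(sequence)
  as.integer(lengths(regmatches(s, gregexpr("G", s, fixed = TRUE))))
}

#' Guanine-corrected molar amounts and splice-site choice fractions
#'
#' Divides each species' band intensity by its guanosine count to get a
#' molar-scale amount, then reports the X_S usage fraction
#' `molar_XS / (molar_XS + molar_XL)` and, when a pre-mRNA band is present,
#' the spliced fraction `(molar_XS + molar_XL) / (pre + molar_XS +
#' molar_XL)`.
#'
#' @param speciesTable data.frame with columns `species` (`pre_mRNA`,
#'   `mRNA_XL`, `mRNA_XS`), `intensity` and `g_count` (the latter can
#'   alternatively be supplied via `gCounts`).
#' @param gCounts optional named integer vector of G counts per species.
#' @param ligand,concentration condition labels carried into the result.
#' @param gCorrection set `FALSE` to skip the guanine correction (for
#'   demonstrating the labeling bias); molar amounts then equal raw
#'   intensities.
#' @return one-row data.frame: `ligand`, `concentration`, `fraction_xs`,
#'   `spliced_fraction`, `molar_pre`, `molar_xl`, `molar_xs`. Fractions are
#'   `NA` when their denominator is zero or a needed species is absent.
#' @export
correctAndFraction <- function(speciesTable, gCounts = NULL,
                               ligand = "control", concentration = 0,
                               gCorrection = TRUE) {
  st <- speciesTable
  if (!is.null(gCounts)) st$g_count <- gCounts[st$species]
  if (!all(c("species", "intensity", "g_count") %in% names(st)))
    stop("need columns species, intensity, g_count", call. = FALSE)
  if (any(st$intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (any(st$g_count < 1)) stop("g_count must be >= 1", call. = FALSE)
  molar <- if (gCorrection) st$intensity / st$g_count else st$intensity
  names(molar) <- st$species
  mXS <- if ("mRNA_XS" %in% names(molar)) molar[["mRNA_XS"]] else NA_real_
  mXL <- if ("mRNA_XL" %in% names(molar)) molar[["mRNA_XL"]] else NA_real_
  mPre <- if ("pre_mRNA" %in% names(molar)) molar[["pre_mRNA"]]
          else NA_real_
  if (is.na(mXS) || is.na(mXL))
    stop("both mRNA_XS and mRNA_XL intensities are required", call. = FALSE)
  fracXS <- if (mXS + mXL > 0) mXS / (mXS + mXL) else NA_real_
  spliced <- if (!is.na(mPre) && mPre + mXS + mXL > 0)
    (mXS + mXL) / (mPre + mXS + mXL) else NA_real_
  data.frame(ligand = ligand, concentration = concentration,
             fraction_xs = fracXS, spliced_fraction = spliced,
             molar_pre = mPre, molar_xl = mXL, molar_xs = mXS,
             stringsAsFactors = FALSE)
}

#' Tidy dose-response table of splice-site choice
#'
#' Stacks per-condition results ordered by concentration (zero/DMSO first).
#' Replicates of the same (ligand, concentration) are aggregated as mean with
#' sample SD.
#'
#' @param results list of one-row data.frames from [correctAndFraction()].
#' @return data.frame: `ligand`, `concentration`, `fraction_xs`,
#'   `fraction_xs_sd`, `spliced_fraction`, `spliced_fraction_sd`,
#'   `n_replicates`.
#' @export
doseResponse <- function(results) {
  if (!length(results)) stop("need at least one condition", call. = FALSE)
  df <- do.call(rbind, results)
  key <- interaction(df$ligand, df$concentration, drop = TRUE)
  agg <- lapply(split(df, key), function(g) {
    data.frame(ligand = g$ligand[1L], concentration = g$concentration[1L],
               fraction_xs = mean(g$fraction_xs),
               fraction_xs_sd = if (nrow(g) > 1L) stats::sd(g$fraction_xs)
                                else NA_real_,
               spliced_fraction = mean(g$spliced_fraction),
               spliced_fraction_sd = if (nrow(g) > 1L)
                 stats::sd(g$spliced_fraction) else NA_real_,
               n_replicates = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$concentration, out$ligand), ]
  rownames(out) <- NULL
  out
}

#' Ligand-induced relative change in usage of one 5' splice site
#'
#' The ratio of a site's molar usage fraction with ligand to its usage
#' without (1 = no change). Usage is the site's molar amount divided by the
#' total RNA (pre-mRNA + both mRNAs) when pre-mRNA was quantified in both
#' conditions, otherwise by total mRNA; `denominator` forces one or the
#' other.
#'
#' @param resultLigand,resultControl one-row data.frames from
#'   [correctAndFraction()].
#' @param site `"XS"` or `"XL"`.
#' @param denominator `"auto"`, `"total"` (pre + mRNAs) or `"mRNA"`.
#' @return single numeric ratio (`NA` when control usage is 0).
#' @export
relativeChange <- function(resultLigand, resultControl,
                           site = c("XS", "XL"),
                           denominator = c("auto", "total", "mRNA")) {
  site <- match.arg(site)
  denominator <- match.arg(denominator)
  usage <- function(r) {
    m <- if (site == "XS") r$molar_xs else r$molar_xl
    tot <- r$molar_xs + r$molar_xl
    if (denominator == "total" ||
        (denominator == "auto" && !is.na(r$molar_pre) &&
         !is.na(resultLigand$molar_pre) && !is.na(resultControl$molar_pre)))
      tot <- tot + r$molar_pre
    if (is.na(tot) || tot <= 0) return(NA_real_)
    m / tot
  }
  uL <- usage(resultLigand)
  uC <- usage(resultControl)
  if (is.na(uC) || uC == 0) return(NA_real_)
  uL / uC
}
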