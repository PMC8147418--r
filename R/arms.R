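#' Autosomal chromosome arm definition
#'
#' The canonical set of autosomal chromosome arms used throughout the package.
#' The 44 autosomal arms are listed in karyotype order; the five acrocentric
#' short arms (13p, 14p, 15p, 21p, 22p) carry `included = FALSE`, leaving the
#' 39 arms conventionally scored in arm-level copy-number analyses. Sex
#' chromosomes are excluded entirely.
#'
#' @return A data frame with columns `arm_id` (e.g. `"1p"`, `"20q"`),
#'   `chromosome` (integer 1-22), `arm_letter` (`"p"` or `"q"`) and
#'   `included` (logical).
#' @examples
#' arms <- arm_definition()
#' sum(arms$included) # 39
#' @export
arm_definition <- function() {
  chrom <- rep(1:22, each = 2L)
  letter <- rep(c("p", "q"), times = 22L)
  arm_id <- paste0(chrom, letter)
  acrocentric_p <- c("13p", "14p", "15p", "21p", "22p")
  data.frame(
    arm_id = arm_id,
    chromosome = chrom,
    arm_letter = letter,
    included = !(arm_id %in% acrocentric_p),
    stringsAsFactors = FALSE
  )
}

#' Included arm identifiers
#'
#' @param arms An arm definition table, by default [arm_definition()].
#' @return Character vector of the 39 included arm ids in karyotype order.
#' @export
included_arms <- function(arms = arm_definition()) {
  arms$arm_id[arms$included]
}

#' Synthetic cytoband table for simulated genomes
#'
#' A deliberately simple, fully synthetic cytoband table in the UCSC
#' `cytoBand.txt` dialect (chrom, 0-based start, end, band, stain) covering
#' chromosomes 1-22, with two bands per arm. Chromosome lengths shrink
#' linearly with chromosome number and the centromere sits at 40% of each
#' chromosome. It exists so that coordinate-based gene/probe-to-arm
#' assignment can be exercised without shipping a genome annotation; it does
#' not reproduce real human band boundaries.
#'
#' @return Data frame with columns `chrom`, `start`, `end`, `band`, `stain`.
#' @export
synthetic_cytobands <- function() {
  rows <- lapply(1:22, function(ch) {
    len <- 250e6 - (ch - 1L) * 9e6
    cen <- round(0.4 * len)
    half_p <- floor(cen / 2)
    half_q <- cen + floor((len - cen) / 2)
    data.frame(
      chrom = paste0("chr", ch),
      start = c(0, half_p, cen, half_q),
      end = c(half_p, cen, half_q, len),
      band = c("p12", "p11", "q11", "q12"),
      stain = c("gneg", "gpos50", "gpos50", "gneg"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Normalize chromosome labels ("chr1", "1", " 1 ") to integer 1..22; NA otherwise.
normalize_chrom <- function(chrom) {
  ch <- sub("^chr", "", trimws(as.character(chrom)), ignore.case = TRUE)
  out <- suppressWarnings(as.integer(ch))
  out[!(out %in% 1:22)] <- NA_integer_
  out
}
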