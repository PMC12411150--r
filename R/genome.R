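#' Define a genome as ordered chromosomes with centromere positions
#'
#' A genome definition is the coordinate authority for the whole package:
#' its chromosome order fixes the genome-wide bin ordering, and the
#' centromere midpoint splits each chromosome into its p and q arms.
#' All coordinates are 0-based half-open base pairs.
#'
#' @param chrom character vector of unique chromosome names, in the order
#'   they should appear genome-wide.
#' @param length integer-ish vector of chromosome lengths in bp (> 0).
#' @param centromere_mid centromere midpoint per chromosome, in bp,
#'   strictly inside `(0, length)`.
#' @return A `data.frame` of class `"genome_def"` with columns `chrom`,
#'   `length`, `centromere_mid`.
#' @seealso [hg19_genome()], [make_bins()]
#' @export
genome_definition <- function(chrom, length, centromere_mid) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  centromere_mid <- as.numeric(centromere_mid)
  if (base::length(chrom) == 0L) stop("empty genome definition")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (base::length(length) != base::length(chrom) ||
      base::length(centromere_mid) != base::length(chrom))
    stop("chrom, length and centromere_mid must have equal length")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  if (any(centromere_mid <= 0) || any(centromere_mid >= length))
    stop("centromere_mid must lie strictly inside (0, length)")
  g <- data.frame(chrom = chrom, length = length,
                  centromere_mid = centromere_mid,
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_def", "data.frame")
  g
}

#' Bundled hg19-style genome definition (chr1-22, chrX)
#'
#' Chromosome lengths and approximate centromere midpoints for the hg19
#' human assembly, built in code so no download or external file is needed.
#' Centromere midpoints are the midpoints of the UCSC hg19 centromere gaps,
#' rounded to 0.1 Mb -- precise enough to label 200-kb bins with their arm.
#'
#' @return A [genome_definition()] object with 23 chromosomes.
#' @export
hg19_genome <- function() {
  genome_definition(
    chrom = paste0("chr", c(1:22, "X")),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566, 155270560),
    centromere_mid = c(1.250e8, 9.33e7, 9.10e7, 5.04e7, 4.84e7,
                       6.10e7, 5.99e7, 4.56e7, 4.90e7, 4.02e7,
                       5.37e7, 3.58e7, 1.79e7, 1.76e7, 1.90e7,
                       3.66e7, 2.40e7, 1.72e7, 2.65e7, 2.75e7,
                       1.32e7, 1.47e7, 6.06e7)
  )
}

#' Read a genome definition from a TSV file
#'
#' Expects a header line and columns `chrom`, `length`, `centromere_mid`.
#'
#' @param path path to the TSV file.
#' @return A [genome_definition()] object.
#' @export
read_genome <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "length", "centromere_mid")
  if (!all(need %in% names(d)))
    stop("genome TSV needs columns: ", paste(need, collapse = ", "))
  genome_definition(d$chrom, d$length, d$centromere_mid)
}

#' Tile a genome into fixed-width bins with arm labels
#'
#' Cuts every chromosome into consecutive `bin_size` windows in genome
#' order. Terminal partial bins are kept with their true width, so each
#' base of each chromosome belongs to exactly one bin. A bin's arm is `p`
#' when its midpoint lies before the centromere midpoint, otherwise `q`
#' (a midpoint exactly at the centromere is labelled `q`).
#'
#' @param genome a [genome_definition()] object.
#' @param bin_size bin width in bp (default 200 kb, the resolution at
#'   which shallow sequencing supports stable copy-number estimates).
#' @return A `data.frame` of class `"bin_grid"` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `arm`, `width`, carrying the
#'   genome and bin size as attributes.
#' @examples
#' g <- genome_definition("chr1", 450000, 200000)
#' make_bins(g, 200000)   # 3 bins, last of width 50 kb
#' @export
make_bins <- function(genome, bin_size = 200000) {
  if (!inherits(genome, "genome_def")) stop("genome must be a genome_definition()")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a single positive number")
  pieces <- lapply(seq_len(nrow(genome)), function(k) {
    len <- genome$length[k]
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    mid <- (starts + ends) / 2
    data.frame(chrom = genome$chrom[k], start = starts, end = ends,
               arm = ifelse(mid < genome$centromere_mid[k], "p", "q"),
               width = ends - starts, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  attr(grid, "genome") <- genome
  attr(grid, "bin_size") <- bin_size
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Arm label for an interval
#'
#' @param chrom chromosome name.
#' @param start,end interval in 0-based half-open bp.
#' @param genome a [genome_definition()].
#' @return `"p"` or `"q"` from the interval midpoint versus the
#'   centromere midpoint (ties go to `q`).
#' @export
assign_arm <- function(chrom, start, end, genome) {
  k <- match(chrom, genome$chrom)
  if (is.na(k)) stop("unknown chromosome: ", chrom)
  if ((start + end) / 2 < genome$centromere_mid[k]) "p" else "q"
}

#' Grid bin indices overlapping a gene locus
#'
#' @param locus a list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open bp).
#' @param grid a [make_bins()] grid.
#' @return Integer vector of row indices of `grid` whose bins overlap
#'   `[start, end)`; always non-empty for an on-grid locus.
#' @export
gene_bins <- function(locus, grid) {
  if (!inherits(grid, "bin_grid")) stop("grid must be a bin_grid")
  if (!(locus$chrom %in% grid$chrom))
    stop("locus chromosome not in grid: ", locus$chrom)
  if (locus$start >= locus$end) stop("locus start must be < end")
  idx <- which(grid$chrom == locus$chrom &
               grid$start < locus$end & grid$end > locus$start)
  if (length(idx) == 0L)
    stop("locus lies outside gridded coordinates: ", locus$chrom,
         ":", locus$start, "-", locus$end)
  idx
}

#' Bundled cancer-gene loci (hg19)
#'
#' Canonical hg19 placements for the recurrently altered colorectal genes
#' tracked by the package: EGFR and ERBB2 (amplification targets), MYC
#' (8q24 amplification), and the 18q21 tumor suppressors SMAD4 and DCC
#' (copy-number loss targets). Coordinates are gene bodies, 0-based
#' half-open.
#'
#' @return A `data.frame` with columns `symbol`, `chrom`, `start`, `end`,
#'   `cytoband_label`.
#' @export
default_gene_loci <- function() {
  data.frame(
    symbol = c("EGFR", "MYC", "SMAD4", "DCC", "ERBB2"),
    chrom = c("chr7", "chr8", "chr18", "chr18", "chr17"),
    start = c(55086714, 128748314, 48556582, 49866541, 37844392),
    end   = c(55324313, 128753680, 48611411, 51057784, 37884915),
    cytoband_label = c("7p11.2", "8q24.21", "18q21.2", "18q21.2", "17q12"),
    stringsAsFactors = FALSE
  )
}

#' Read gene loci from a BED-like TSV
#'
#' Columns: `chrom`, `start`, `end`, `symbol` (0-based half-open), with a
#' header line; an optional `cytoband_label` column is carried through.
#'
#' @param path path to the TSV file.
#' @return A gene-locus `data.frame` as in [default_gene_loci()].
#' @export
read_gene_loci <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "symbol")
  if (!all(need %in% names(d)))
    stop("gene locus TSV needs columns: ", paste(need, collapse = ", "))
  if (any(d$start >= d$end)) stop("gene loci must have start < end")
  if (is.null(d$cytoband_label)) d$cytoband_label <- NA_character_
  d[, c("symbol", "chrom", "start", "end", "cytoband_label")]
}
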