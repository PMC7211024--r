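#' Genome size estimate of maize NC358
#'
#' The 2,272,400,000 bp estimate used throughout the NC358 titration
#' study as the denominator of NG(x), assembled-% and coverage-fold
#' statistics.
#'
#' @return Genome size in bp.
#' @export
nc358_genome_size <- function() 2272400000

#' Published summary statistics of the NC358 titration assemblies
#'
#' The per-condition summary table of the maize NC358 depth/read-length
#' titration: eight Falcon-Canu assemblies of serially downsampled (20-75
#' fold, 21 kb subread N50) and length-shifted (11 kb and 16 kb N50 at 50
#' fold) PacBio read sets. These printed values are inputs for arithmetic
#' checks (assembled %, coverage folds, contig-count fold changes); the
#' package does not re-run the assemblers.
#'
#' @return A data.frame, one row per condition, with subread/corrected
#'   base totals (Gb), read N25/N50 (kb), contig counts and totals,
#'   contig N50 (Mb), assembled and gap percentages, effective assembly
#'   size (Gb), and Falcon/Canu CPU core hours.
#' @export
nc358_table1 <- function() {
  data.frame(
    experiment = c("21k_20x", "21k_30x", "21k_40x", "21k_50x",
                   "21k_60x", "21k_75x", "11k_50x", "16k_50x"),
    subreads_gb = c(45.62, 68.16, 91.01, 113.89, 136.80, 171.08,
                    113.63, 113.60),
    subread_coverage = c(20, 30, 40, 50, 60, 75, 50, 50),
    max_read_kb = c(89.6, 103.3, 103.3, 103.3, 103.3, 103.3, 88.3, 69.8),
    subread_n25_kb = c(30.1, 30.1, 30.1, 30.1, 30.1, 30.1, 14.5, 21.6),
    subread_n50_kb = c(21.2, 21.2, 21.2, 21.2, 21.2, 21.2, 11.1, 16.8),
    corrected_gb = c(25.11, 48.13, 66.05, 82.96, 88.93, 100.90,
                     79.26, 80.22),
    corrected_coverage = c(11, 21, 29, 37, 39, 44, 35, 35),
    contig_number = c(10563, 2015, 641, 407, 360, 327, 5683, 1036),
    contig_total_gb = c(1.60, 2.11, 2.12, 2.12, 2.13, 2.13, 2.10, 2.12),
    longest_contig_mb = c(1.06, 11.50, 47.89, 76.00, 79.68, 78.40,
                          4.37, 21.45),
    contig_n50_mb = c(0.18, 1.82, 7.48, 16.27, 22.12, 24.54, 0.56, 4.24),
    assembled_pct = c(70.4, 92.8, 93.3, 93.3, 93.7, 93.7, 92.4, 93.2),
    gap_pct = c(24.50, 0.90, 0.43, 0.34, 0.31, 0.31, 2.01, 0.48),
    effective_size_gb = c(1.33, 1.67, 1.70, 1.72, 1.74, 1.75, 1.68, 1.70),
    falcon_cpu_hour = c(1563, 4162, 6363, 10693, 12386, 32950,
                        9721, 9224),
    canu_cpu_hour = c(1860, 4036, 5959, 7914, 8849, 11520, 6400, 7174),
    stringsAsFactors = FALSE
  )
}
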