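#' Configuration for an end-to-end demonstration run
#'
#' Resolves all tunables of the demo workflow. Defaults are scaled to a
#' desk-size synthetic genome; `genome_size` here is the size of the
#' simulated genome, while real-data workflows would set it to their own
#' estimate (e.g. 2,272,400,000 bp for maize NC358).
#'
#' @param genome_spec a [genome_spec()] for the simulated genome.
#' @param full_depth depth of the simulated full read set.
#' @param depth_ladder descending depths to titrate to.
#' @param target_n50 read N50 of the full set (bp).
#' @param shift_n50s read N50s of the two length-shifted datasets (bp).
#' @param k k-mer length for effective size.
#' @param max_interspace array clustering gap (bp).
#' @param min_gap_run N-run threshold for contig splitting.
#' @param seed integer seed for every stochastic stage.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(genome_spec = titrasm::genome_spec(),
                       full_depth = 75,
                       depth_ladder = c(60, 50, 40, 30, 20),
                       target_n50 = 21000,
                       shift_n50s = c(16000, 11000),
                       k = 150, max_interspace = 100000,
                       min_gap_run = 10, seed = 1L) {
  assert_scalar_number(full_depth, "full_depth", min = 1)
  assert_scalar_number(target_n50, "target_n50", min = 1)
  assert_scalar_number(k, "k", min = 1)
  assert_scalar_number(max_interspace, "max_interspace", min = 1)
  assert_scalar_number(min_gap_run, "min_gap_run", min = 1)
  if (any(depth_ladder >= full_depth))
    stop("depth_ladder must lie below full_depth")
  structure(list(genome_spec = genome_spec, full_depth = full_depth,
                 depth_ladder = as.numeric(depth_ladder),
                 target_n50 = target_n50,
                 shift_n50s = as.numeric(shift_n50s), k = k,
                 max_interspace = max_interspace,
                 min_gap_run = min_gap_run, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a flat key = value config file
#'
#' Lines of the form `key = value` (comments with `#`) override the
#' defaults of [run_config()]; numeric vectors are comma-separated.
#'
#' @param path config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop(sprintf("malformed config line: %s", lines[bad][1L]))
  vals <- lapply(kv, function(p) as.numeric(strsplit(p[[2L]], ",")[[1L]]))
  names(vals) <- vapply(kv, `[[`, "", 1L)
  known <- c("full_depth", "depth_ladder", "target_n50", "shift_n50s",
             "k", "max_interspace", "min_gap_run", "seed")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config key: %s", unknown[1L]))
  do.call(run_config, vals)
}

# severity mapping: lower depth -> more breaks; an explicit stand-in for
# the fragmentation of low-depth assemblies, not a fitted model
breaks_for_depth <- function(depth) {
  list(repeat_rate = 1600 / depth^1.5, unique_rate = 400 / depth^1.5)
}

#' Run the end-to-end demonstration workflow
#'
#' Simulates a genome and a full-depth read set, titrates the reads down
#' a depth ladder, shifts the full set onto two shorter length
#' distributions, degrades the genome at severities matched to the depth
#' ladder, and assembles a per-condition metrics table (contig count,
#' NG50, assembled %, gap %, effective size, repeat-array completeness,
#' telomere motif counts). Deterministic for a fixed config.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes `metrics.tsv`,
#'   `read_stats.tsv`, and `report.json`.
#' @param quiet suppress progress messages.
#' @return A list of class `DemoReport`: `config_echo`, `read_stats`
#'   (per depth/shift), `metrics` (per degraded condition), `genome`
#'   summary.
#' @export
run_demo <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "simulate-genome"
  res <- tryCatch({
    say("[%s] building synthetic genome (seed %d)", stage, config$seed)
    genome <- build_genome(config$genome_spec)
    gsize <- sum(Biostrings::width(genome$assembly$seq))

    stage <- "simulate-reads"
    say("[%s] simulating %gx reads, target N50 %g", stage,
        config$full_depth, config$target_n50)
    rc <- read_sim_config(depth = config$full_depth,
                          target_n50 = config$target_n50,
                          seed = config$seed)
    reads <- simulate_reads(genome, rc, sequences = FALSE)

    stage <- "titrate"
    say("[%s] serial titration to %s", stage,
        paste0(config$depth_ladder, "x", collapse = ","))
    tit <- serial_downsample(reads, config$depth_ladder, gsize,
                             seed = config$seed)

    stage <- "shift-lengths"
    shift_stats <- list()
    for (n50 in config$shift_n50s) {
      tgt_cfg <- read_sim_config(depth = if (length(config$depth_ladder))
                                   config$depth_ladder[1L] else 50,
                                 target_n50 = n50, seed = config$seed + 7L)
      targets <- simulate_read_lengths(
        stats::setNames(gsize, "g"), tgt_cfg)$reads$length
      sh <- match_length_distribution(reads, targets,
                                      seed = config$seed + 11L)
      shift_stats[[sprintf("shift_%dk", round(n50 / 1000))]] <-
        c(length_stats(sh$reads$reads$length),
          skipped = length(sh$skipped_lengths))
    }

    stage <- "degrade"
    conditions <- c(config$full_depth, config$depth_ladder)
    metrics <- list()
    truth_sizes <- with(genome$truth,
                        tapply(end - start, label, sum))
    # telomeres are counted by motif, not scanned as a monomer: a 7-mer at
    # 0.8 identity would match background everywhere
    classes <- setdiff(intersect(names(genome$monomers),
                                 unique(genome$truth$label)), "telomere")
    for (d in conditions) {
      say("[degrade] depth %gx equivalent", d)
      rates <- breaks_for_depth(d)
      deg <- degrade_assembly(genome, degrade_config(
        breaks_per_mb_unique = rates$unique_rate,
        breaks_per_mb_repeat = rates$repeat_rate,
        drop_fraction = 0.3, gap_policy = "ngap", seed = config$seed))
      rep_rpt <- repeat_report(deg$assembly, genome$monomers[classes],
                               max_interspace = config$max_interspace,
                               truth_sizes = truth_sizes)
      cg <- contiguity_report(deg$assembly, genome_size = gsize,
                              k = config$k,
                              min_gap_run = config$min_gap_run)
      metrics[[sprintf("%gx", d)]] <- data.frame(
        condition = sprintf("%gx", d),
        contig_count = cg$contig_count,
        ng50 = cg$ngx_curve[["50"]],
        assembled_pct = cg$assembled_pct,
        gap_pct = round(cg$gap_pct, 3),
        effective_size_bp = cg$effective_size_bp,
        array_completeness_pct = round(100 *
          sum(rep_rpt$by_class$repeat_bp) /
          sum(rep_rpt$by_class$truth_bp), 2),
        telomere_motifs = count_telomere_motifs(deg$assembly$seq),
        stringsAsFactors = FALSE)
    }
    metrics <- do.call(rbind, metrics)
    rownames(metrics) <- NULL

    read_stats <- rbind(
      data.frame(dataset = sprintf("%gx", config$full_depth),
                 as.data.frame(unclass(length_stats(reads$reads$length))),
                 skipped = 0),
      do.call(rbind, lapply(seq_along(config$depth_ladder), function(i)
        data.frame(dataset = sprintf("%gx", config$depth_ladder[i]),
                   as.data.frame(unclass(tit$stats[[i]])), skipped = 0))),
      do.call(rbind, lapply(names(shift_stats), function(nm)
        data.frame(dataset = nm,
                   as.data.frame(shift_stats[[nm]][c(
                     "count", "total", "max", "n25", "n50", "skipped")])))))
    rownames(read_stats) <- NULL

    structure(list(
      config_echo = config[setdiff(names(config), "genome_spec")],
      genome = list(size_bp = gsize,
                    chromosomes = length(genome$assembly$seq),
                    truth_features = nrow(genome$truth)),
      read_stats = read_stats, metrics = metrics),
      class = "DemoReport")
  }, error = function(e) {
    stop(sprintf("demo failed at stage '%s' (seed %d): %s", stage,
                 config$seed, conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(res$metrics, file.path(out_dir, "metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$read_stats, file.path(out_dir, "read_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res[c("config_echo", "genome", "metrics")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.DemoReport <- function(x, ...) {
  cat(sprintf("DemoReport: genome %.0f bp, %d conditions\n",
              x$genome$size_bp, nrow(x$metrics)))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
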