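#' Pipeline configuration
#'
#' Bundles paths, pond structure and tuning parameters for a full analysis
#' run. Validation is eager: every mutant line must map to exactly one
#' wild-type, every referenced line needs a VCF, and all files must exist.
#'
#' @param genome_fasta reference FASTA path.
#' @param gff3 gene-model GFF3 path.
#' @param vcfs named character vector, line id -> VCF path (wild-type lines
#'   included).
#' @param ponds named list, wild-type id -> character vector of member
#'   mutant line ids.
#' @param outdir output directory for report files.
#' @param thresholds a [filter_thresholds()].
#' @param window_sizes window sizes in bp for the hotspot scan (default
#'   1 Mb and 100 kb).
#' @param hf_fold HF fold threshold (default 20).
#' @param upstream_bp,downstream_bp context windows for [locate_mutations()].
#' @param generation Mn generation index (default 6).
#' @param mode back-projection mode (default `"table"`).
#' @param genome_length rate denominator in bp; `NULL` means the span of
#'   `genome_fasta`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, gff3, vcfs, ponds, outdir,
                            thresholds = filter_thresholds(),
                            window_sizes = c(1e6, 1e5), hf_fold = 20,
                            upstream_bp = 1000, downstream_bp = 1000,
                            generation = 6, mode = "table",
                            genome_length = NULL) {
  if (is.null(names(vcfs)) || any(names(vcfs) == "")) {
    stop_badarg("vcfs must be a named vector (line id -> path)")
  }
  members <- unlist(ponds, use.names = FALSE)
  if (any(duplicated(members))) {
    stop_badarg("a mutant line maps to more than one wild-type")
  }
  missing_vcf <- setdiff(c(names(ponds), members), names(vcfs))
  if (length(missing_vcf)) {
    stop_badarg("no VCF configured for line(s): ",
                paste(missing_vcf, collapse = ", "))
  }
  for (p in c(genome_fasta, gff3, unname(vcfs))) {
    if (!file.exists(p)) stop_badarg("input file not found: ", p)
  }
  structure(list(genome_fasta = genome_fasta, gff3 = gff3, vcfs = vcfs,
                 ponds = ponds, outdir = outdir, thresholds = thresholds,
                 window_sizes = window_sizes, hf_fold = hf_fold,
                 upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 generation = generation, mode = mode,
                 genome_length = genome_length),
            class = "pipeline_config")
}

#' Serialize / reload a pipeline configuration (flat JSON)
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return the path ([write_config()]) or a `pipeline_config`
#'   ([read_config()]).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$vcfs <- as.list(x$vcfs)        # keep line-id keys in the JSON object
  x$ponds <- lapply(x$ponds, as.list)
  x$thresholds <- unclass(x$thresholds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ponds <- lapply(x$ponds, unlist)
  pipeline_config(x$genome_fasta, x$gff3, unlist(x$vcfs), x$ponds, x$outdir,
                  thresholds = do.call(filter_thresholds, as.list(x$thresholds)),
                  window_sizes = x$window_sizes, hf_fold = x$hf_fold,
                  upstream_bp = x$upstream_bp, downstream_bp = x$downstream_bp,
                  generation = x$generation, mode = x$mode,
                  genome_length = x$genome_length)
}

#' Run the full analysis pipeline
#'
#' derive -> filter -> classify -> spectrum -> effects -> hotspots -> rates.
#' Every analysis stage is deterministic given the inputs; rerunning with
#' the same configuration reproduces every output byte for byte. Reports
#' are plain TSV/BED under `config$outdir`; exclusion counters are both
#' logged (via `message`) and written to `run_log.tsv`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list: mutations (all lines), line_summaries,
#'   pond_summaries (spectra), rates (pond_summary objects), effects,
#'   locations, hf_regions, colocalization, log, files.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[cibmut] ", ...)
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)

  genome <- read_genome_fasta(config$genome_fasta)
  contig_lengths <- setNames(Biostrings::width(genome), names(genome))
  annotation <- read_gff3_annotation(config$gff3, contig_lengths)
  genome_length <- if (is.null(config$genome_length)) {
    sum(as.numeric(contig_lengths))
  } else config$genome_length

  log <- c(n_records_read = 0, n_filtered = 0, n_shared = 0, n_dedup = 0,
           n_mnv = 0, n_len_excluded = 0, n_induced = 0)
  mutations <- list()
  line_summaries <- list()
  pond_spectra <- list()
  rates <- list()
  line_rows <- list()

  for (wt in names(config$ponds)) {
    members <- config$ponds[[wt]]
    say("pond ", wt, ": ", length(members), " mutant line(s)")
    wt_rec <- read_vcf(config$vcfs[[wt]], wt)
    log["n_records_read"] <- log["n_records_read"] + nrow(wt_rec)
    wt_kept <- apply_hard_filters(wt_rec, config$thresholds)
    for (l in members) {
      rec <- read_vcf(config$vcfs[[l]], l)
      log["n_records_read"] <- log["n_records_read"] + nrow(rec)
      kept <- apply_hard_filters(rec, config$thresholds)
      log["n_filtered"] <- log["n_filtered"] + attr(kept, "n_removed")
      ind <- derive_induced(kept, wt_kept, config$thresholds)
      dl <- attr(ind, "log")
      log["n_shared"] <- log["n_shared"] + dl[["n_shared"]]
      log["n_dedup"] <- log["n_dedup"] + dl[["n_dedup"]]
      log["n_mnv"] <- log["n_mnv"] + dl[["n_mnv"]]
      log["n_len_excluded"] <- log["n_len_excluded"] + dl[["n_len_excluded"]]
      log["n_induced"] <- log["n_induced"] + nrow(ind)
      mutations[[l]] <- ind
      line_summaries[[l]] <- summarize_spectrum(ind, l)
    }
    pond_id <- paste0("pond_", wt)
    pond <- mutation_pond(pond_id, wt, members)
    pond_spectra[[pond_id]] <- pond_aggregate(line_summaries, pond)
    m6 <- vapply(members, function(l) nrow(mutations[[l]]), 0)
    rates[[pond_id]] <- pond_summary(pond_id, m6, n = config$generation,
                                     mode = config$mode,
                                     genome_length = genome_length)
    for (l in members) {
      s <- line_summaries[[l]]
      line_rows[[l]] <- data.frame(
        wildtype_id = wt, line_id = l, total = s$n_total, sbs = s$n_sbs,
        indels = s$n_ins + s$n_del,
        estimated_m1 = back_project(s$n_total, config$generation, config$mode),
        pond_rate = format_rate(rates[[pond_id]]$rate),
        stringsAsFactors = FALSE)
    }
  }
  all_mut <- do.call(rbind, c(mutations, list(make.row.names = FALSE)))

  say("classifying genomic context and coding effects")
  locations <- locate_mutations(all_mut, annotation, config$upstream_bp,
                                config$downstream_bp)
  loc_tab <- as.data.frame(table(line_id = all_mut$line_id,
                                 category = locations),
                           stringsAsFactors = FALSE)
  names(loc_tab)[3] <- "count"
  loc_tab <- loc_tab[order(loc_tab$line_id, loc_tab$category), ]
  eff <- effect_table(all_mut, annotation, genome)

  say("scanning windowed mutation frequencies")
  hf_all <- list()
  coloc_rows <- list()
  for (pond_id in names(pond_spectra)) {
    wt <- sub("^pond_", "", pond_id)
    members <- config$ponds[[wt]]
    pm <- all_mut[all_mut$line_id %in% members, , drop = FALSE]
    pond_total <- nrow(pm)
    for (ws in config$window_sizes) {
      for (ch in names(contig_lengths)) {
        for (cls in c("SBS", "InDel")) {
          tr <- window_counts(pm, ch, contig_lengths[[ch]], ws, cls)
          hf <- call_hf_regions(tr, config$hf_fold, pond_total)
          if (nrow(hf)) {
            hf$name <- sprintf("%s:%s:%g", pond_id, cls, ws)
            hf_all[[length(hf_all) + 1L]] <- hf
          }
        }
        tr_s <- window_counts(pm, ch, contig_lengths[[ch]], ws, "SBS")
        tr_i <- window_counts(pm, ch, contig_lengths[[ch]], ws, "InDel")
        co <- colocalization(call_hf_regions(tr_s, config$hf_fold, pond_total),
                             call_hf_regions(tr_i, config$hf_fold, pond_total),
                             contig_lengths[[ch]], ws)
        coloc_rows[[length(coloc_rows) + 1L]] <- data.frame(
          pond = pond_id, chrom = ch, window_size = ws,
          n_sbs_windows = co$n_sbs_windows,
          n_indel_windows = co$n_indel_windows, shared = co$shared,
          jaccard = co$jaccard, p_hyper = co$p_hyper,
          stringsAsFactors = FALSE)
      }
    }
  }
  hf_regions <- if (length(hf_all)) do.call(rbind, hf_all) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mclass = character(), n_mut = integer(), fold = numeric(),
               fraction_of_total = numeric(), name = character())
  coloc <- do.call(rbind, coloc_rows)

  files <- write_pipeline_reports(config$outdir, line_rows, pond_spectra,
                                  loc_tab, eff, hf_regions, coloc, log)
  say("done: ", log[["n_induced"]], " induced mutations across ",
      length(mutations), " lines")
  invisible(list(mutations = all_mut, line_summaries = line_summaries,
                 pond_spectra = pond_spectra, rates = rates, effects = eff,
                 locations = loc_tab, hf_regions = hf_regions,
                 colocalization = coloc, log = log, files = files,
                 genome_length = genome_length))
}

write_pipeline_reports <- function(outdir, line_rows, pond_spectra, loc_tab,
                                   eff, hf_regions, coloc, log) {
  fp <- function(x) file.path(outdir, x)
  wt <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character()
  files["line_summary"] <- wt(do.call(rbind, line_rows), fp("line_summary.tsv"))
  spec_rows <- do.call(rbind, lapply(names(pond_spectra), function(p) {
    s <- pond_spectra[[p]]
    data.frame(pond = p, sub_type = names(s$sub_counts),
               count = as.integer(s$sub_counts), stringsAsFactors = FALSE)
  }))
  files["spectrum"] <- wt(spec_rows, fp("spectrum_by_pond.tsv"))
  hist_rows <- do.call(rbind, lapply(names(pond_spectra), function(p) {
    s <- pond_spectra[[p]]
    data.frame(pond = p, length = 1:50, ins_count = s$indel_hist[, "ins"],
               del_count = s$indel_hist[, "del"], stringsAsFactors = FALSE)
  }))
  files["indel_hist"] <- wt(hist_rows, fp("indel_hist_by_pond.tsv"))
  files["locations"] <- wt(loc_tab, fp("locations.tsv"))
  files["effects"] <- wt(eff$table, fp("effects.tsv"))
  files["effect_calls"] <- wt(eff$calls, fp("effect_calls.tsv"))
  hf_bed <- hf_regions
  if (nrow(hf_bed)) hf_bed$mclass <- hf_bed$name
  files["hf_regions"] <- fp("hf_regions.bed")
  write_hf_bed(hf_bed, files[["hf_regions"]])
  files["colocalization"] <- wt(coloc, fp("colocalization.tsv"))
  files["run_log"] <- wt(data.frame(counter = names(log), value = unname(log)),
                         fp("run_log.tsv"))
  files
}
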