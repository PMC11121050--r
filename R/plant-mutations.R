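#' Plant a synthetic induced-mutation set on a toy genome
#'
#' Samples `n_mutations` distinct positions (per-bp sampling weight `fold`
#' inside hotspot regions, 1 elsewhere), draws mutation classes and types
#' from `params`, and returns both a truth table and per-line VCF-style
#' records carrying synthetic QD/FS/MQ/GQ annotations that pass the default
#' hard filters. A configurable set of shared background variants (present
#' in the wild-type and every mutant line) exercises induced-set derivation
#' by subtraction, and optional decoy records with failing annotations
#' exercise the filters.
#'
#' For every planted coding SBS the truth table records the oracle effect
#' category obtained by full-CDS retranslation before/after the change
#' (synonymous / nonsynonymous / nonsense); coding InDels are labelled
#' frameshift or inframe_indel from the coding-length change mod 3.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param annotation `genome_annotation` matching `genome`.
#' @param params a [spectrum_params()] object.
#' @param hotspots a [hotspot_spec()] or `NULL`.
#' @param n_mutations number of induced mutations to plant (>= 1).
#' @param seed integer RNG seed (single stream per fixture).
#' @param line_ids mutant line names; each mutation is assigned to one line
#'   uniformly at random.
#' @param wildtype_id name of the wild-type line.
#' @param n_background shared background variants present in the wild type
#'   and in every mutant line (default 500).
#' @param n_fail decoy records per mutant line given failing QD/FS/MQ/GQ
#'   values (default 0); decoys are not part of the truth table.
#' @param hom_fraction proportion of induced records emitted as homozygous
#'   (1/1) genotypes; the remainder are heterozygous (0/1).
#' @return list with `truth` (data.frame: line_id, chrom, pos, ref, alt,
#'   class, sub_type, indel_len, in_hotspot, oracle_effect), `records`
#'   (VCF-style records: line_id, chrom, pos, ref, alt, qd, fs, mq, gq, gt,
#'   origin), `line_ids`, `wildtype_id`, `seed`.
#' @export
plant_mutations <- function(genome, annotation, params = spectrum_params(),
                            hotspots = NULL, n_mutations, seed,
                            line_ids = "mut1", wildtype_id = "WT",
                            n_background = 500, n_fail = 0,
                            hom_fraction = 0.8) {
  stopifnot(inherits(params, "spectrum_params"))
  if (n_mutations < 1) stop_badarg("n_mutations must be >= 1")
  if (!is.null(hotspots)) validate_hotspots(hotspots, annotation)
  set.seed(seed)
  chrom_len <- annotation$contig_lengths
  total_bp <- sum(as.numeric(chrom_len))
  n_need <- n_mutations + n_background
  if (n_need > total_bp / 2) {
    stop_badarg(sprintf("requested %d variants exceed available positions (%g bp genome)",
                        n_need, total_bp))
  }
  chars <- lapply(seq_along(genome), function(i) strsplit(as.character(genome[[i]]), "")[[1]])
  names(chars) <- names(genome)

  pos_tab <- sample_positions(chrom_len, hotspots, n_need)
  induced_idx <- seq_len(n_mutations)
  bg_idx <- if (n_background > 0) n_mutations + seq_len(n_background) else integer()

  truth <- draw_mutations(pos_tab[induced_idx, , drop = FALSE], chars, chrom_len, params)
  truth$line_id <- sample(line_ids, n_mutations, replace = TRUE)
  truth$in_hotspot <- in_hotspot(truth$chrom, truth$pos, hotspots)
  truth$oracle_effect <- oracle_effects(truth, annotation, genome)
  truth <- truth[, c("line_id", "chrom", "pos", "ref", "alt", "class",
                     "sub_type", "indel_len", "in_hotspot", "oracle_effect")]

  gt <- ifelse(runif(n_mutations) < hom_fraction, "1/1", "0/1")
  records <- data.frame(line_id = truth$line_id, chrom = truth$chrom,
                        pos = truth$pos, ref = truth$ref, alt = truth$alt,
                        qd = 20, fs = 1.0, mq = 60, gq = 99L, gt = gt,
                        origin = "induced", stringsAsFactors = FALSE)

  if (n_background > 0) {
    bg <- draw_mutations(pos_tab[bg_idx, , drop = FALSE], chars, chrom_len,
                         spectrum_params(ti_fraction = params$ti_fraction,
                                         indel_fraction = 0))
    bg_rec <- data.frame(line_id = NA_character_, chrom = bg$chrom, pos = bg$pos,
                         ref = bg$ref, alt = bg$alt, qd = 20, fs = 1.0, mq = 60,
                         gq = 99L, gt = "1/1", origin = "background",
                         stringsAsFactors = FALSE)
    records <- rbind(records,
                     do.call(rbind, lapply(c(wildtype_id, line_ids), function(l) {
                       r <- bg_rec; r$line_id <- l; r
                     })))
  }
  if (n_fail > 0) {
    fail <- make_fail_records(chars, chrom_len, pos_tab, n_fail, line_ids)
    records <- rbind(records, fail)
  }
  list(truth = truth, records = records, line_ids = line_ids,
       wildtype_id = wildtype_id, seed = seed)
}

validate_hotspots <- function(hotspots, annotation) {
  if (!nrow(hotspots)) return(invisible())
  unknown <- setdiff(hotspots$chrom, names(annotation$contig_lengths))
  if (length(unknown)) stop_badarg("hotspot on unknown chromosome: ", unknown[1])
  len <- annotation$contig_lengths[hotspots$chrom]
  if (any(hotspots$end > len)) stop_badarg("hotspot region outside contig bounds")
  invisible()
}

# weighted distinct position sampling: per-bp weight fold in hotspots, 1
# elsewhere; returns data.frame(chrom, pos) of n distinct (chrom, pos) pairs
sample_positions <- function(chrom_len, hotspots, n) {
  segs <- list()
  for (ch in names(chrom_len)) {
    hs <- if (is.null(hotspots)) NULL else hotspots[hotspots$chrom == ch, , drop = FALSE]
    bounds <- c(0, if (!is.null(hs) && nrow(hs)) rbind(hs$start, hs$end), chrom_len[[ch]])
    folds <- rep(1, length(bounds) - 1)
    if (!is.null(hs) && nrow(hs)) folds[seq(2, by = 2, length.out = nrow(hs))] <- hs$fold
    keep <- diff(bounds) > 0
    segs[[ch]] <- data.frame(chrom = ch, start = bounds[-length(bounds)][keep],
                             end = bounds[-1][keep], fold = folds[keep])
  }
  segs <- do.call(rbind, segs)
  w <- segs$fold * (segs$end - segs$start)
  out <- data.frame(chrom = character(), pos = integer())
  seen <- character()
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 100L)
    si <- sample.int(nrow(segs), m, replace = TRUE, prob = w)
    pos <- segs$start[si] + floor(runif(m) * (segs$end[si] - segs$start[si])) + 1L
    cand <- data.frame(chrom = segs$chrom[si], pos = as.integer(pos))
    key <- paste(cand$chrom, cand$pos)
    ok <- !duplicated(key) & !(key %in% seen)
    cand <- cand[ok, , drop = FALSE]
    seen <- c(seen, key[ok])
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

# draw ref/alt, class and type for each sampled position
draw_mutations <- function(pos_tab, chars, chrom_len, params) {
  n <- nrow(pos_tab)
  chrom <- pos_tab$chrom
  pos <- pos_tab$pos
  is_indel <- runif(n) < params$indel_fraction
  ref <- alt <- character(n)
  sub_type <- rep(NA_character_, n)
  indel_len <- integer(n)
  for (i in seq_len(n)) {
    base <- chars[[chrom[i]]][pos[i]]
    if (!is_indel[i]) {
      if (runif(1) < params$ti_fraction) {
        a <- TRANSITION_PARTNER[[base]]
      } else {
        cand <- setdiff(BASES, c(base, TRANSITION_PARTNER[[base]]))
        wts <- params$sub_weights[paste0(base, ">", cand)]
        a <- sample(cand, 1, prob = wts)
      }
      ref[i] <- base; alt[i] <- a
      sub_type[i] <- paste0(base, ">", a)
    } else {
      len <- sample.int(50L, 1, prob = params$indel_len_dist)
      if (runif(1) < params$ins_del_balance) {
        ref[i] <- base
        alt[i] <- paste0(base, paste(sample(BASES, len, replace = TRUE), collapse = ""))
      } else {
        if (pos[i] + len > chrom_len[[chrom[i]]]) pos[i] <- chrom_len[[chrom[i]]] - len
        ref[i] <- paste(chars[[chrom[i]]][pos[i]:(pos[i] + len)], collapse = "")
        alt[i] <- substr(ref[i], 1, 1)
      }
      indel_len[i] <- len
    }
  }
  cls <- classify_mutation(ref, alt)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             class = cls$mclass, sub_type = sub_type, indel_len = indel_len,
             stringsAsFactors = FALSE)
}

in_hotspot <- function(chrom, pos, hotspots) {
  if (is.null(hotspots) || !nrow(hotspots)) return(rep(FALSE, length(pos)))
  out <- logical(length(pos))
  for (i in seq_len(nrow(hotspots))) {
    out <- out | (chrom == hotspots$chrom[i] &
                    pos > hotspots$start[i] & pos <= hotspots$end[i])
  }
  out
}

make_fail_records <- function(chars, chrom_len, used_pos, n_fail, line_ids) {
  fails <- list(list(qd = 1.0, fs = 1.0, mq = 60, gq = 99L),
                list(qd = 20, fs = 80.0, mq = 60, gq = 99L),
                list(qd = 20, fs = 1.0, mq = 30, gq = 99L),
                list(qd = 20, fs = 1.0, mq = 60, gq = 10L))
  rows <- list()
  for (l in line_ids) {
    for (j in seq_len(n_fail)) {
      repeat {
        ch <- sample(names(chrom_len), 1)
        p <- sample.int(chrom_len[[ch]], 1)
        if (!any(used_pos$chrom == ch & used_pos$pos == p)) break
      }
      base <- chars[[ch]][p]
      f <- fails[[(j - 1L) %% 4L + 1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = l, chrom = ch, pos = p, ref = base,
        alt = TRANSITION_PARTNER[[base]], qd = f$qd, fs = f$fs, mq = f$mq,
        gq = f$gq, gt = "1/1", origin = "fail", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ---- truth-table effect oracle: full-CDS retranslation ----------------------

oracle_effects <- function(truth, annotation, genome) {
  models <- transcript_models(annotation)
  out <- rep(NA_character_, nrow(truth))
  if (!length(models)) return(out)
  impact <- c(frameshift = 4, nonsense = 3, nonsynonymous = 2,
              inframe_indel = 1.5, synonymous = 1)
  for (i in seq_len(nrow(truth))) {
    calls <- character()
    for (m in models) {
      if (m$chrom != truth$chrom[i]) next
      eff <- oracle_effect_one(truth$pos[i], truth$ref[i], truth$alt[i],
                               truth$class[i], m, genome)
      if (!is.na(eff)) calls[m$transcript_id] <- eff
    }
    if (length(calls)) {
      ord <- order(-impact[calls], names(calls))
      out[i] <- calls[ord[1]]
    }
  }
  out
}

oracle_effect_one <- function(pos, ref, alt, class, model, genome) {
  if (class == "SBS") {
    hit <- any(pos >= model$cds[, 1] & pos <= model$cds[, 2])
    if (!hit) return(NA_character_)
    before <- spliced_cds(model, genome)
    after <- spliced_cds(model, genome, sub_pos = pos, sub_base = alt)
    p0 <- translate_dna(before)
    p1 <- translate_dna(after)
    if (identical(p0, p1)) return("synonymous")
    d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
    if (length(d) && substr(p1, d[1], d[1]) == "*") return("nonsense")
    return("nonsynonymous")
  }
  # InDel: coding-length change mod 3 on the CDS overlap
  clen <- coding_overlap_len(pos, ref, alt, model)
  if (clen == 0) return(NA_character_)
  if (clen %% 3 == 0) "inframe_indel" else "frameshift"
}

# number of coding bases inserted/removed by a VCF-anchored InDel
coding_overlap_len <- function(pos, ref, alt, model) {
  if (nchar(alt) > nchar(ref)) {      # insertion after `pos`
    inside <- any(pos >= model$cds[, 1] & pos < model$cds[, 2])
    if (inside) nchar(alt) - nchar(ref) else 0L
  } else {                            # deletion of pos+1 .. pos+len
    del <- c(pos + 1L, pos + nchar(ref) - nchar(alt))
    sum(pmax(0L, pmin(model$cds[, 2], del[2]) - pmax(model$cds[, 1], del[1]) + 1L))
  }
}

# spliced CDS on the coding strand, optionally with one genomic base replaced
spliced_cds <- function(model, genome, sub_pos = NULL, sub_base = NULL) {
  seq <- as.character(genome[[model$chrom]])
  parts <- apply(model$cds, 1, function(iv) substr(seq, iv[1], iv[2]))
  if (!is.null(sub_pos)) {
    for (k in seq_len(nrow(model$cds))) {
      iv <- model$cds[k, ]
      if (sub_pos >= iv[1] && sub_pos <= iv[2]) {
        substr(parts[k], sub_pos - iv[1] + 1L, sub_pos - iv[1] + 1L) <- sub_base
      }
    }
  }
  s <- paste(parts, collapse = "")
  if (model$strand == "-") reverse_complement(s) else s
}
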