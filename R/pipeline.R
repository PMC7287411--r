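# End-to-end orchestration: simulate/read -> detect -> statistics ->
# context -> reports, with deterministic file outputs.

#' Assemble a pipeline run configuration
#'
#' Validates paths and parameters and fills in defaults. The effective
#' configuration is serialized into the run directory by
#' \code{\link{run_pipeline}}.
#'
#' @param maf,tree,gff3 Input paths (MAF alignment, Newick tree, GFF3 gene
#'   models).
#' @param out_dir Output directory for the run.
#' @param reference Reference species identifier.
#' @param gene2term Optional path to a gene-to-term TSV
#'   (\code{gene_id<TAB>term_id[<TAB>term_name]}) for enrichment.
#' @param lambda Neutral scale; \code{NULL} to estimate from the data.
#' @param min_species Minimum present species per usable column.
#' @param min_element_length,max_gap_run,rs_floor Element-calling
#'   parameters.
#' @param alpha Significance threshold for the rapid and species-specific
#'   tests.
#' @param distance \code{"jc69"} or \code{"raw"}.
#' @param baseline_mode Species-test baseline: \code{"per_species"} or
#'   \code{"global"}.
#' @param correct_dispersion Divide chi-squared statistics by the estimated
#'   phylogenetic variance-inflation factor (default TRUE).
#' @param flank Context flank width in bp.
#' @param bins Region-length bin breakpoints for the context summary.
#' @param groups Named list of group contrasts, each a list with elements
#'   \code{a} and \code{b} (species vectors); \code{NULL} for an automatic
#'   outcrossing-vs-selfing contrast when the Oryza panel species are
#'   present.
#' @param seed Seed recorded in the configuration (the analysis stages are
#'   deterministic; the seed exists for provenance).
#' @return A \code{run_config} list.
#' @export
run_config <- function(maf, tree, gff3, out_dir, reference,
                       gene2term = NULL, lambda = NULL, min_species = 4,
                       min_element_length = 10, max_gap_run = 3,
                       rs_floor = 0, alpha = 0.001,
                       distance = c("jc69", "raw"),
                       baseline_mode = c("per_species", "global"),
                       correct_dispersion = TRUE, flank = 2000,
                       bins = c(0, 100, 500, 1000, Inf), groups = NULL,
                       seed = 1) {
  distance <- match.arg(distance)
  baseline_mode <- match.arg(baseline_mode)
  for (p in c(maf = maf, tree = tree, gff3 = gff3)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (!is.null(gene2term) && !file.exists(gene2term)) {
    stop("input file not found: ", gene2term)
  }
  stopifnot(min_species >= 3, min_element_length >= 1, max_gap_run >= 0,
            alpha > 0, alpha < 1, flank > 0)
  structure(list(maf = maf, tree = tree, gff3 = gff3, out_dir = out_dir,
                 reference = reference, gene2term = gene2term,
                 lambda = lambda, min_species = min_species,
                 min_element_length = min_element_length,
                 max_gap_run = max_gap_run, rs_floor = rs_floor,
                 alpha = alpha, distance = distance,
                 baseline_mode = baseline_mode,
                 correct_dispersion = correct_dispersion, flank = flank,
                 bins = bins, groups = groups, seed = seed,
                 version = as.character(utils::packageVersion("cnsevol"))),
            class = "run_config")
}

#' Run the full CNS rapid-evolution pipeline
#'
#' Reads the alignment, tree and gene models; calls conserved elements;
#' computes per-element substitution profiles, the pooled baseline and the
#' dispersion factor; flags rapidly evolving and species-specific rapidly
#' evolving regions; classifies regions by genomic context; and (when a
#' gene-to-term table is given) runs term enrichment on the genes
#' associated with rapid regions. All outputs are deterministic: re-running
#' with identical inputs and configuration yields byte-identical files.
#'
#' Files written to \code{out_dir}: \code{cns_elements.bed},
#' \code{element_stats.tsv}, \code{rapid_regions.tsv},
#' \code{species_specific.tsv}, \code{group_contrasts.tsv},
#' \code{context.tsv}, \code{context_summary.tsv}, \code{enrichment.tsv}
#' (optional), \code{run_log.txt}, \code{config_effective.json}.
#'
#' @param config A \code{\link{run_config}}.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("read_inputs", {
    list(blocks = read_maf(config$maf),
         tree = read_newick(config$tree),
         genes = read_gff3(config$gff3),
         gene2term = if (!is.null(config$gene2term)) {
           g2t <- utils::read.table(config$gene2term, sep = "\t",
                                    header = TRUE, stringsAsFactors = FALSE)
           names(g2t)[1:2] <- c("gene_id", "term_id")
           g2t
         })
  })
  note("stage read_inputs: ", length(inputs$blocks), " blocks, ",
       length(inputs$genes), " gene models, ",
       length(inputs$tree$tip.label), " species in tree")

  det <- stage("detect", {
    detect_cns(inputs$blocks, inputs$tree, config$reference,
               gene_models = inputs$genes, lambda = config$lambda,
               min_species = config$min_species,
               min_element_length = config$min_element_length,
               max_gap_run = config$max_gap_run,
               rs_floor = config$rs_floor)
  })
  elements <- det$elements
  note("stage detect: ", nrow(elements), " elements, lambda=",
       sprintf("%.6g", det$lambda))
  write_bed(data.frame(chrom = elements$chrom, start = elements$start,
                       end = elements$end, name = elements$element_id,
                       score = elements$mean_rs * 100,
                       strand = rep("+", nrow(elements)),
                       stringsAsFactors = FALSE),
            file.path(out, "cns_elements.bed"))

  if (!nrow(elements)) {
    warning("no conserved elements called; writing empty reports")
    empty_outputs(out, config)
    note("stage stats: skipped (no elements)")
    writeLines(log_lines, file.path(out, "run_log.txt"))
    write_effective_config(config, out)
    return(invisible(out))
  }

  stats_res <- stage("stats", {
    profiles <- element_profiles(inputs$blocks, elements,
                                 correction = config$distance)
    baseline <- compute_baseline(profiles)
    disp <- if (isTRUE(config$correct_dispersion)) {
      estimate_dispersion(profiles, baseline)
    } else list(c = 1, c_s = 1)
    rapid <- rapid_region_tests(profiles, baseline, alpha = config$alpha,
                                dispersion = disp$c)
    rapid_ids <- rapid$element_id[rapid$is_rapid]
    spec <- species_specific_tests(
      profiles[rapid_ids], baseline, alpha = config$alpha,
      dispersion = disp$c_s, baseline_mode = config$baseline_mode)
    list(profiles = profiles, baseline = baseline, disp = disp,
         rapid = rapid, rapid_ids = rapid_ids, spec = spec)
  })
  note("stage stats: baseline p0=", sprintf("%.6g", stats_res$baseline$p0),
       " (unweighted mean ",
       sprintf("%.6g", stats_res$baseline$unweighted_mean), "), dispersion=",
       sprintf("%.6g", stats_res$disp$c), ", ",
       length(stats_res$rapid_ids), " rapid regions")

  loc <- elements[, c("element_id", "chrom", "start", "end", "n_columns",
                      "sum_rs", "mean_rs")]
  es <- merge(loc, stats_res$rapid[, c("element_id", "n", "mean_frequency",
                                       "D", "N", "freq")],
              by = "element_id", sort = FALSE)
  es <- es[order(es$chrom, es$start), ]
  write_report(es, file.path(out, "element_stats.tsv"))

  rr <- merge(loc[, c("element_id", "chrom", "start", "end")],
              stats_res$rapid, by = "element_id", sort = FALSE)
  rr <- rr[order(rr$chrom, rr$start), ]
  write_report(rr, file.path(out, "rapid_regions.tsv"))

  sp <- stats_res$spec
  if (nrow(sp)) sp <- sp[order(sp$element_id, sp$species), ]
  write_report(sp, file.path(out, "species_specific.tsv"))

  gc_res <- stage("group_contrasts", {
    groups <- config$groups
    if (is.null(groups)) {
      tips <- inputs$tree$tip.label
      outx <- intersect(c("Orufipogon", "Olongistaminata"), tips)
      if (length(outx) && length(setdiff(tips, outx))) {
        groups <- list(outcrossing_vs_selfing = list(
          a = outx, b = setdiff(tips, outx)))
      } else groups <- list()
    }
    rows <- lapply(names(groups), function(nm) {
      g <- groups[[nm]]
      if (!length(stats_res$rapid_ids)) return(NULL)
      cmp <- compare_group_frequencies(stats_res$profiles,
                                       stats_res$rapid_ids, g$a, g$b)
      data.frame(contrast = nm,
                 group_a = paste(g$a, collapse = ","),
                 group_b = paste(g$b, collapse = ","),
                 freq_a = cmp$freq_a, freq_b = cmp$freq_b,
                 D_a = cmp$D_a, N_a = cmp$N_a, D_b = cmp$D_b, N_b = cmp$N_b,
                 chi2 = cmp$chi2, p = cmp$p, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, NA)]
    if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame(contrast = character(), group_a = character(),
                    group_b = character(), freq_a = numeric(),
                    freq_b = numeric(), D_a = numeric(), N_a = numeric(),
                    D_b = numeric(), N_b = numeric(), chi2 = numeric(),
                    p = numeric(), stringsAsFactors = FALSE)
  })
  write_report(gc_res, file.path(out, "group_contrasts.tsv"))

  ctx_res <- stage("context", {
    intervals <- build_context_intervals(inputs$genes, flank = config$flank)
    ctx <- classify_regions(elements, intervals)
    is_rapid <- elements$element_id %in% stats_res$rapid_ids
    ctx_tab <- merge(
      data.frame(element_id = elements$element_id,
                 is_rapid = is_rapid, stringsAsFactors = FALSE),
      ctx, by = "element_id", sort = FALSE)
    ctx_tab <- ctx_tab[order(ctx_tab$element_id, ctx_tab$category,
                             ctx_tab$gene_id),
                       c("element_id", "category", "gene_id", "is_rapid")]
    sum_all <- summarize_context_distribution(ctx, elements,
                                              bins = config$bins)
    sum_all$set <- "all_elements"
    rap_el <- elements[is_rapid, , drop = FALSE]
    sum_rap <- summarize_context_distribution(
      ctx[ctx$element_id %in% rap_el$element_id, , drop = FALSE],
      rap_el, bins = config$bins)
    sum_rap$set <- "rapid"
    smry <- rbind(sum_all, sum_rap)
    flagged <- stats_res$spec[stats_res$spec$flagged, , drop = FALSE]
    if (nrow(flagged)) {
      ss_el <- merge(flagged[, c("element_id", "species")],
                     elements, by = "element_id", sort = FALSE)
      sum_ss <- summarize_context_distribution(
        ctx[ctx$element_id %in% ss_el$element_id, , drop = FALSE],
        ss_el, bins = config$bins, group = "species")
      sum_ss$set <- "species_specific"
      names(sum_ss)[names(sum_ss) == "group"] <- "species"
      smry$species <- "all"
      smry <- rbind(smry, sum_ss[, c(names(smry))])
    } else {
      smry$species <- "all"
    }
    smry <- smry[, c("set", "species", "category", "length_bin", "count")]
    smry <- smry[order(smry$set, smry$species, smry$category,
                       smry$length_bin), ]
    list(ctx = ctx, ctx_tab = ctx_tab, smry = smry)
  })
  write_report(ctx_res$ctx_tab, file.path(out, "context.tsv"))
  write_report(ctx_res$smry, file.path(out, "context_summary.tsv"))
  note("stage context: ", length(unique(ctx_res$ctx$element_id)),
       " elements with gene-context associations")

  if (!is.null(inputs$gene2term)) {
    enr <- stage("enrichment", {
      study <- sort(unique(ctx_res$ctx$gene_id[
        ctx_res$ctx$element_id %in% stats_res$rapid_ids]))
      background <- sort(unique(vapply(inputs$genes,
                                       function(m) m$gene_id, "")))
      enrich_terms(study, background, inputs$gene2term)
    })
    write_report(enr, file.path(out, "enrichment.tsv"))
    note("stage enrichment: ", nrow(enr), " terms tested")
  }

  writeLines(log_lines, file.path(out, "run_log.txt"))
  write_effective_config(config, out)
  invisible(out)
}

empty_outputs <- function(out, config) {
  hdr <- function(...) {
    stats::setNames(as.data.frame(
      lapply(c(...), function(x) character(0))), c(...))
  }
  write_report(hdr("element_id", "chrom", "start", "end", "n_columns",
                   "sum_rs", "mean_rs", "n", "mean_frequency", "D", "N",
                   "freq"),
               file.path(out, "element_stats.tsv"))
  write_report(hdr("element_id", "chrom", "start", "end", "n",
                   "mean_frequency", "D", "N", "freq", "chi2", "p",
                   "is_rapid", "low_expected", "p_bh"),
               file.path(out, "rapid_regions.tsv"))
  write_report(hdr("element_id", "species", "f_s", "D_s", "N_s", "freq",
                   "p0_s", "chi2", "p", "flagged", "low_expected", "p_bh"),
               file.path(out, "species_specific.tsv"))
  write_report(hdr("contrast", "group_a", "group_b", "freq_a", "freq_b",
                   "D_a", "N_a", "D_b", "N_b", "chi2", "p"),
               file.path(out, "group_contrasts.tsv"))
  write_report(hdr("element_id", "category", "gene_id", "is_rapid"),
               file.path(out, "context.tsv"))
  write_report(hdr("set", "species", "category", "length_bin", "count"),
               file.path(out, "context_summary.tsv"))
  if (!is.null(config$gene2term)) {
    write_report(hdr("term_id", "term_name", "k", "K", "m", "M", "p",
                     "p_adj"),
                 file.path(out, "enrichment.tsv"))
  }
}

write_effective_config <- function(config, out) {
  cfg <- unclass(config)
  cfg$bins <- as.character(cfg$bins)  # keep Inf JSON-safe
  jsonlite::write_json(cfg, file.path(out, "config_effective.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

#' Map BED intervals back to block column spans
#'
#' Locates, for each interval, the alignment block whose reference row
#' covers it and the corresponding column span. This lets the statistics
#' stage consume a BED of elements written by an earlier detection run.
#'
#' @param blocks List of \code{alignment_block} objects.
#' @param bed data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{name}.
#' @param reference Reference species.
#' @return Element table with \code{element_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{block_id}, \code{col_start},
#'   \code{col_end}.
#' @export
elements_from_bed <- function(blocks, bed, reference) {
  if (is.null(bed$name)) bed$name <- sprintf("region_%d", seq_len(nrow(bed)))
  rows <- lapply(seq_len(nrow(bed)), function(i) {
    for (b in blocks) {
      if (!reference %in% b$rows$species) next
      r <- b$rows[b$rows$species == reference, ]
      if (r$chrom != bed$chrom[i]) next
      pos <- column_ref_positions(b, reference)
      inside <- !is.na(pos) & pos >= bed$start[i] & pos < bed$end[i]
      if (!any(inside)) next
      w <- which(inside)
      return(data.frame(element_id = bed$name[i], chrom = bed$chrom[i],
                        start = bed$start[i], end = bed$end[i],
                        block_id = b$block_id, col_start = w[1],
                        col_end = w[length(w)], stringsAsFactors = FALSE))
    }
    stop("no block covers interval ", bed$chrom[i], ":", bed$start[i], "-",
         bed$end[i], " on the reference")
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
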