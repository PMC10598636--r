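#' Read a pipeline run configuration
#'
#' YAML with an `input` block (paths), an optional `stages` vector and a
#' `params` block. Every parameter has a documented default; a config that
#' is written back with [yaml::write_yaml()] round-trips losslessly.
#'
#' @param path YAML file.
#' @return A `RunConfig` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

default_stages <- c("stats", "ssr", "repeats", "conformations",
                    "readsupport", "mtpt", "editing")

as_run_config <- function(cfg) {
  cfg$stages <- if (is.null(cfg$stages)) default_stages else cfg$stages
  p <- cfg$params
  defaults <- list(ssr_preset = "relaxed", min_repeat_length = 50L,
                   flank = 1000L, min_anchor = 100L, min_margin = 20L,
                   evalue_cutoff = 1e-5, min_reads = 1L,
                   rf_repeats_min_length = 100L, band_width = 100L)
  for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  cfg$params <- p
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  structure(cfg, class = "RunConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order: per-molecule statistics, SSR
#' scan, dispersed-repeat search, conformation construction, long-read
#' conformation support and recombination frequency, MTPT detection, and
#' RNA-editing calling. Writes per-stage TSVs plus one machine-readable
#' JSON run report under `out_dir`. Stage errors propagate with the stage
#' name; non-requested stages are skipped.
#'
#' @param cfg A `RunConfig` (list or [read_run_config()] output). Expected
#'   `input` paths: `fasta` (mitogenome, required), `reads` (FASTQ/FASTA),
#'   `plastid_fasta`, `plastid_gff`, `cds_fasta`, `cdna_fasta`,
#'   `pairs_tsv`.
#' @return The run report (invisibly written as `report.json`).
#' @export
run_all <- function(cfg) {
  if (!inherits(cfg, "RunConfig")) cfg <- as_run_config(cfg)
  p <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$input$fasta) || !file.exists(cfg$input$fasta))
    stop("stage input: mitogenome FASTA missing (input$fasta)")
  genome <- read_fasta(cfg$input$fasta)
  report <- list(parameters = p, stages_run = character(0))
  stage <- function(name, code) {
    if (!name %in% cfg$stages) return(NULL)
    message("[mitoforma] stage ", name)
    tryCatch(code, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  res <- stage("stats", {
    genome_stats(genome)
  })
  if (!is.null(res)) {
    report$stats <- res
    report$stages_run <- c(report$stages_run, "stats")
    write_tsv(res, file.path(cfg$out_dir, "stats.tsv"))
  }

  res <- stage("ssr", {
    thr <- ssr_thresholds(p$ssr_preset)
    ssrs <- merge_compound(find_ssrs_genome(genome, thr), thr)
    list(table = ssrs, summary = ssr_summary(ssrs))
  })
  if (!is.null(res)) {
    report$ssr <- res$summary
    report$stages_run <- c(report$stages_run, "ssr")
    write_tsv(res$table, file.path(cfg$out_dir, "ssr.tsv"))
  }

  pairs <- stage("repeats", {
    self_align(genome, min_length = p$min_repeat_length)
  })
  if (!is.null(pairs)) {
    report$repeats <- pairs
    report$stages_run <- c(report$stages_run, "repeats")
    write_tsv(pairs, file.path(cfg$out_dir, "hsps.tsv"))
  }

  conf_sets <- stage("conformations", {
    if (is.null(pairs)) stop("requires the repeats stage")
    cand <- pairs[pairs$length >= p$rf_repeats_min_length, , drop = FALSE]
    sets <- lapply(seq_len(nrow(cand)), function(i) {
      build_local_conformations(genome, cand[i, ], flank = p$flank)
    })
    names(sets) <- cand$hsp_id
    sets
  })
  if (!is.null(conf_sets)) {
    report$stages_run <- c(report$stages_run, "conformations")
    for (id in names(conf_sets)) {
      write_conformations(conf_sets[[id]],
                          file.path(cfg$out_dir,
                                    paste0("conformations_", id, ".fa")))
    }
  }

  res <- stage("readsupport", {
    if (is.null(conf_sets)) stop("requires the conformations stage")
    if (is.null(cfg$input$reads)) stop("no reads input configured")
    reads <- read_reads(cfg$input$reads)
    reports <- lapply(names(conf_sets), function(id) {
      if (nrow(reads) == 0L) {
        return(data.frame(hsp_id = id, n1 = 0L, n2 = 0L, n3 = 0L, n4 = 0L,
                          n_ambiguous = 0L, n_unusable = 0L, rf = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          supported_minor = FALSE,
                          note = "no informative reads",
                          stringsAsFactors = FALSE))
      }
      asn <- classify_reads(reads, conf_sets[[id]],
                            min_anchor = p$min_anchor,
                            min_margin = p$min_margin,
                            band_width = p$band_width)
      rep <- recombination_report(asn, hsp_id = id,
                                  min_reads = p$min_reads)
      rep$note <- if (sum(rep[c("n1", "n2", "n3", "n4")]) == 0)
        "no informative reads" else NA_character_
      rep
    })
    do.call(rbind, c(reports, make.row.names = FALSE))
  })
  if (!is.null(res)) {
    report$recombination <- res
    report$stages_run <- c(report$stages_run, "readsupport")
    write_tsv(res, file.path(cfg$out_dir, "recombination.tsv"))
  }

  res <- stage("mtpt", {
    if (is.null(cfg$input$plastid_fasta)) stop("no plastome input configured")
    plastome <- read_fasta(cfg$input$plastid_fasta)
    fr <- find_mtpts(genome, plastome, evalue_cutoff = p$evalue_cutoff)
    if (!is.null(cfg$input$plastid_gff)) {
      fr <- genes_in_fragments(fr, read_gff_genes(cfg$input$plastid_gff))
    }
    list(fragments = fr, summary = mtpt_summary(fr, genome))
  })
  if (!is.null(res)) {
    report$mtpt <- res$summary
    report$stages_run <- c(report$stages_run, "mtpt")
    write_tsv(res$fragments, file.path(cfg$out_dir, "mtpt.tsv"))
  }

  res <- stage("editing", {
    if (is.null(cfg$input$cds_fasta) || is.null(cfg$input$cdna_fasta))
      stop("editing requires cds_fasta and cdna_fasta inputs")
    cds <- read_fasta(cfg$input$cds_fasta, default_topology = "linear")
    cdna <- read_fasta(cfg$input$cdna_fasta, default_topology = "linear")
    pairs_map <- if (!is.null(cfg$input$pairs_tsv)) {
      utils::read.delim(cfg$input$pairs_tsv, stringsAsFactors = FALSE)
    } else {
      data.frame(cdna_id = names(cdna), gene_id = names(cdna),
                 stringsAsFactors = FALSE)
    }
    calls <- lapply(seq_len(nrow(pairs_map)), function(i) {
      g <- pairs_map$gene_id[i]
      call_edits(cds[[g]]$seq, cdna[[pairs_map$cdna_id[i]]]$seq, g)
    })
    events <- do.call(rbind, lapply(calls, `[[`, "events"))
    list(events = events, spectrum = editing_spectrum(events))
  })
  if (!is.null(res)) {
    report$editing <- res$spectrum
    report$stages_run <- c(report$stages_run, "editing")
    write_tsv(res$events, file.path(cfg$out_dir, "edits.tsv"))
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(report)
}
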