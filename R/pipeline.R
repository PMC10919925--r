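# Shared table I/O and the end-to-end pipeline driver.

#' Read or write a TSV table
#'
#' All tabular interchange in the package is UTF-8 TSV with a header row;
#' lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("input table not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param x data frame to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a simulated dataset back from a directory
#'
#' Round-trip counterpart of [write_simulation()]: every file the
#' generator writes is re-parseable by the package's own readers.
#'
#' @param dir directory written by [write_simulation()].
#' @return A list shaped like a [simulate_triangle()] result (`ogs`,
#'   `og_table`, `categories`, `ortholog_map`, `reference_annotation`,
#'   `clades`, `organelle`, `expression`, `designs`, `truth`).
#' @export
read_simulation <- function(dir) {
  if (!dir.exists(dir)) stop("simulation directory not found: ", dir)
  design_files <- list.files(dir, pattern = "^design_.*\\.json$", full.names = TRUE)
  designs <- lapply(design_files, read_cross_design)
  names(designs) <- vapply(designs, function(d) d$allopolyploid_id, character(1))

  og_files <- sort(list.files(file.path(dir, "ogs"), pattern = "\\.fasta$",
                              full.names = TRUE))
  ogs <- lapply(og_files, read_codon_fasta)
  names(ogs) <- sub("\\.fasta$", "", basename(og_files))

  clade_files <- sort(list.files(file.path(dir, "clades"), pattern = "\\.fasta$",
                                 full.names = TRUE))
  clades <- stats::setNames(vector("list", length(designs)), names(designs))
  for (f in clade_files) {
    fam <- sub("\\.fasta$", "", basename(f))
    cross <- sub("_fam[0-9]+$", "", fam)
    clades[[cross]][[fam]] <- read_codon_fasta(f)
  }

  org_files <- sort(list.files(file.path(dir, "organelle"), pattern = "\\.fasta$",
                               full.names = TRUE))
  organelle <- stats::setNames(vector("list", length(designs)), names(designs))
  for (f in org_files) {
    parts <- strsplit(sub("\\.fasta$", "", basename(f)), "_")[[1]]
    cross <- parts[1]
    compartment <- parts[2]
    gene <- paste(parts[-(1:2)], collapse = "_")
    organelle[[cross]][[compartment]][[gene]] <- read_codon_fasta(f)
  }

  og_table <- read_tsv_table(file.path(dir, "og_table.tsv"))
  categories <- tapply(og_table$category, og_table$og_id, function(x) x[1])
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  list(designs = designs, ogs = ogs, og_table = og_table,
       categories = categories,
       ortholog_map = read_tsv_table(file.path(dir, "ortholog_map.tsv")),
       reference_annotation = read_tsv_table(file.path(dir, "annotation.tsv")),
       clades = clades, organelle = organelle,
       expression = read_tsv_table(file.path(dir, "expression.tsv")),
       truth = truth)
}

#' Run the full analysis pipeline on a triangle dataset
#'
#' Executes, per cross: organelle variant typing and donor inference,
#' retention-bias analysis, quartet conversion classification, site-level
#' conversion scanning, counting-based dN/dS with dS filtering and log2
#' subgenome rate ratios, and expression-bias classification. Every
#' threshold in force is echoed to the run log and recorded in the
#' manifest.
#'
#' @param sim a [simulate_triangle()] result or a directory readable by
#'   [read_simulation()].
#' @param stages subset of
#'   `c("typing", "retention", "quartet", "sites", "dnds", "expression")`.
#' @param ds_cutoff dS cutoff for excluding poorly aligned OGs (default 2).
#' @param epsilon quartet similarity tie tolerance (default 0).
#' @param min_diag minimum parental diagnostic differences for a quartet
#'   call (default 3).
#' @param pseudocount,expression_floor,log2fc_threshold expression
#'   classifier settings (defaults 0.1, 1 FPKM, 1).
#' @param donor_support_threshold minimum donor support (default 0.8).
#' @param verbose echo thresholds and per-stage progress via `message()`.
#' @return A list of per-stage, per-cross results plus a `manifest`
#'   (package version, thresholds, stage list).
#' @export
run_pipeline <- function(sim,
                         stages = c("typing", "retention", "quartet",
                                    "sites", "dnds", "expression"),
                         ds_cutoff = 2, epsilon = 0, min_diag = 3,
                         pseudocount = 0.1, expression_floor = 1,
                         log2fc_threshold = 1,
                         donor_support_threshold = 0.8,
                         verbose = TRUE) {
  if (is.character(sim)) sim <- read_simulation(sim)
  stages <- match.arg(stages, several.ok = TRUE)
  params <- list(ds_cutoff = ds_cutoff, epsilon = epsilon,
                 min_diag = min_diag, pseudocount = pseudocount,
                 expression_floor = expression_floor,
                 log2fc_threshold = log2fc_threshold,
                 donor_support_threshold = donor_support_threshold)
  say <- function(...) if (verbose) message(sprintf(...))
  say("run_pipeline: stages = %s", paste(stages, collapse = ", "))
  for (p in names(params)) say("  param %s = %s", p, format(params[[p]]))

  report <- list(params = params)
  crosses <- names(sim$designs)

  if ("typing" %in% stages) {
    report$typing <- lapply(crosses, function(cross) {
      design <- sim$designs[[cross]]
      summaries <- list()
      for (compartment in names(sim$organelle[[cross]])) {
        recs <- lapply(sim$organelle[[cross]][[compartment]],
                       type_variants, design = design)
        summaries[[compartment]] <- aggregate_typing(
          recs, if (compartment == "plastid") "plastid" else "mitochondrion")
      }
      donor <- infer_maternal_donor(
        summaries, support_threshold = donor_support_threshold)
      say("typing %s: donor %s (support %.3f, %s)", cross,
          donor$genome_id, donor$support, donor$status)
      list(summaries = summaries, donor = donor)
    })
    names(report$typing) <- crosses
  }

  if ("retention" %in% stages) {
    report$retention <- lapply(crosses, function(cross) {
      retention_counts(sim$og_table, sim$categories, sim$designs[[cross]])
    })
    names(report$retention) <- crosses
  }

  if ("quartet" %in% stages) {
    report$quartet <- lapply(crosses, function(cross) {
      design <- sim$designs[[cross]]
      calls <- list()
      for (og in names(sim$ogs)) {
        r <- sim$ogs[[og]]$records
        n_sub <- sum(r$genome == cross & r$role == "subgenome")
        if (n_sub != 2L) next
        calls[[og]] <- classify_quartet(
          sim$ogs[[og]], design, epsilon = epsilon, min_diag = min_diag,
          og_id = og, category = sim$categories[[og]])
      }
      calls_df <- data.frame(
        og_id = vapply(calls, function(x) x$og_id, character(1)),
        category = vapply(calls, function(x) x$category, character(1)),
        call = vapply(calls, function(x) x$call, character(1)),
        o1 = vapply(calls, function(x) x$o1, numeric(1)),
        o2 = vapply(calls, function(x) x$o2, numeric(1)),
        h1 = vapply(calls, function(x) x$h1, numeric(1)),
        h2 = vapply(calls, function(x) x$h2, numeric(1)),
        flag = vapply(calls, function(x) x$flag, character(1)),
        stringsAsFactors = FALSE, row.names = NULL)
      say("quartet %s: %d OGs classified, %d directional", cross,
          nrow(calls_df), sum(calls_df$call %in% c("P_to_M", "M_to_P")))
      list(calls = calls_df, summary = summarize_conversions(calls))
    })
    names(report$quartet) <- crosses
  }

  if ("sites" %in% stages) {
    report$sites <- lapply(crosses, function(cross) {
      design <- sim$designs[[cross]]
      events <- list()
      snps <- numeric(0)
      for (fam in names(sim$clades[[cross]])) {
        ev <- scan_clade_conversions(sim$clades[[cross]][[fam]], design, fam)
        snps[fam] <- attr(ev, "n_diagnostic")
        if (nrow(ev)) {
          ev$family <- fam
          events[[fam]] <- ev
        }
      }
      events <- if (length(events)) {
        do.call(rbind, events)
      } else {
        data.frame(clade_id = character(0), gene_id = character(0),
                   column = integer(0), column_1based = integer(0),
                   direction = character(0), effect = character(0),
                   reciprocal = logical(0), family = character(0),
                   stringsAsFactors = FALSE)
      }
      rownames(events) <- NULL
      tab <- tabulate_families(events_to_family_counts(events, snps))
      say("sites %s: %d diagnostic sites, %d events (M-to-P %d, P-to-M %d)",
          cross, sum(snps), nrow(events),
          attr(tab, "maternally_biased"), attr(tab, "paternally_biased"))
      list(events = events, snps = snps, table = tab)
    })
    names(report$sites) <- crosses
  }

  if ("dnds" %in% stages) {
    report$dnds <- lapply(crosses, function(cross) {
      design <- sim$designs[[cross]]
      rows <- list()
      seqs_m <- character(0)
      seqs_p <- character(0)
      seqs_out <- character(0)
      cats <- character(0)
      for (og in names(sim$ogs)) {
        r <- sim$ogs[[og]]$records
        i_m <- which(r$genome == cross & r$role == "subgenome" & r$origin == "maternal")
        i_p <- which(r$genome == cross & r$role == "subgenome" & r$origin == "paternal")
        i_o <- which(r$role == "outgroup")
        if (length(i_m) != 1L || length(i_p) != 1L || length(i_o) != 1L) next
        est_m <- ng_pairwise(r$sequence[i_m], r$sequence[i_o])
        est_p <- ng_pairwise(r$sequence[i_p], r$sequence[i_o])
        rows[[og]] <- data.frame(
          og_id = og, category = sim$categories[[og]],
          d_s_maternal = est_m$d_s, d_n_maternal = est_m$d_n,
          omega_maternal = est_m$omega,
          d_s_paternal = est_p$d_s, d_n_paternal = est_p$d_n,
          omega_paternal = est_p$omega,
          log2_omega_ratio = as.numeric(log2_omega_ratio(est_p$omega, est_m$omega)),
          max_d_s = max(est_m$d_s, est_p$d_s, na.rm = FALSE),
          stringsAsFactors = FALSE)
        seqs_m[og] <- r$sequence[i_m]
        seqs_p[og] <- r$sequence[i_p]
        seqs_out[og] <- r$sequence[i_o]
        cats[og] <- sim$categories[[og]]
      }
      per_og <- do.call(rbind, rows)
      rownames(per_og) <- NULL
      keep <- per_og$og_id[!is.na(per_og$max_d_s) & per_og$max_d_s <= ds_cutoff]
      say("dnds %s: dS cutoff %.3g kept %d of %d OGs", cross, ds_cutoff,
          length(keep), nrow(per_og))
      concat <- do.call(rbind, lapply(FUNCTIONAL_CATEGORIES, function(cat) {
        ids <- intersect(keep, names(cats)[cats == cat])
        if (length(ids) == 0L) {
          return(data.frame(category = cat, n_ogs = 0L,
                            omega_maternal = NA_real_, omega_paternal = NA_real_,
                            log2_omega_ratio = NA_real_, stringsAsFactors = FALSE))
        }
        em <- ng_pairwise(paste(seqs_m[ids], collapse = ""),
                          paste(seqs_out[ids], collapse = ""))
        ep <- ng_pairwise(paste(seqs_p[ids], collapse = ""),
                          paste(seqs_out[ids], collapse = ""))
        data.frame(category = cat, n_ogs = length(ids),
                   omega_maternal = em$omega, omega_paternal = ep$omega,
                   log2_omega_ratio = as.numeric(log2_omega_ratio(ep$omega, em$omega)),
                   stringsAsFactors = FALSE)
      }))
      list(per_og = per_og, retained = keep, concatenated = concat)
    })
    names(report$dnds) <- crosses
  }

  if ("expression" %in% stages) {
    report$expression <- lapply(crosses, function(cross) {
      x <- sim$expression[sim$expression$cross == cross, , drop = FALSE]
      m_cols <- grep("^m_rep", names(x))
      p_cols <- grep("^p_rep", names(x))
      records <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
        homoeolog_log2fc(as.numeric(x[i, m_cols]), as.numeric(x[i, p_cols]),
                         pseudocount = pseudocount, floor = expression_floor,
                         threshold = log2fc_threshold,
                         og_id = x$og_id[i], category = x$category[i])
      }))
      list(records = records, summary = bias_summary(records))
    })
    names(report$expression) <- crosses
  }

  report$manifest <- list(
    package = "cytonuclear",
    version = as.character(utils::packageVersion("cytonuclear")),
    stages = stages,
    params = params)
  report
}

#' Write the main pipeline tables to a directory
#'
#' Emits per-cross TSVs (donor call, retention summaries, quartet calls
#' and conversion summary, site-conversion events and family table, per-OG
#' and concatenated rates, expression records and summary) plus a JSON
#' manifest recording thresholds. Byte-stable for identical input.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cross in names(report$typing)) {
    d <- report$typing[[cross]]$donor
    write_tsv_table(
      data.frame(cross = cross, donor = d$genome_id, support = d$support,
                 private_fraction = d$private_fraction, status = d$status),
      file.path(dir, paste0("donor_", cross, ".tsv")))
  }
  for (cross in names(report$retention)) {
    write_tsv_table(report$retention[[cross]],
                    file.path(dir, paste0("retention_", cross, ".tsv")))
  }
  for (cross in names(report$quartet)) {
    write_tsv_table(report$quartet[[cross]]$calls,
                    file.path(dir, paste0("quartet_calls_", cross, ".tsv")))
    write_tsv_table(report$quartet[[cross]]$summary,
                    file.path(dir, paste0("quartet_summary_", cross, ".tsv")))
  }
  for (cross in names(report$sites)) {
    write_tsv_table(report$sites[[cross]]$events,
                    file.path(dir, paste0("site_events_", cross, ".tsv")))
    write_tsv_table(report$sites[[cross]]$table,
                    file.path(dir, paste0("site_families_", cross, ".tsv")))
  }
  for (cross in names(report$dnds)) {
    write_tsv_table(report$dnds[[cross]]$per_og,
                    file.path(dir, paste0("rates_per_og_", cross, ".tsv")))
    write_tsv_table(report$dnds[[cross]]$concatenated,
                    file.path(dir, paste0("rates_concatenated_", cross, ".tsv")))
  }
  for (cross in names(report$expression)) {
    write_tsv_table(report$expression[[cross]]$records,
                    file.path(dir, paste0("expression_records_", cross, ".tsv")))
    write_tsv_table(report$expression[[cross]]$summary,
                    file.path(dir, paste0("expression_summary_", cross, ".tsv")))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
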