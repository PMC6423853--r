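# Stage runners and the command-line pipeline: each stage writes TSV
# artifacts carrying the config hash and seed, so reruns are bit-identical
# and every call is auditable.

#' Run the pipeline
#'
#' Executes the requested stages on the template simulation: `simulate`
#' (genomes, repeats, truth), `synteny` (blocks, block stats), and the
#' combined breakpoint/history/stats analysis, ending with a collated
#' report of one row per inversion.
#'
#' @param config A [default_config()] (or one read with [read_config()]).
#' @param stages Character vector among `"simulate"`, `"synteny"`,
#'   `"breakpoints"`, `"history"`, `"stats"`, `"report"`, or `"all"`.
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config = default_config(), stages = "all") {
  all_stages <- c("simulate", "synteny", "breakpoints", "history",
                  "stats", "report")
  if ("all" %in% stages) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config_hash = config_hash(config), seed = config$seed,
               package_version = as.character(utils::packageVersion("paracentric")))
  res <- list()
  sim <- simulate_template(config)
  res$sim <- sim
  if ("simulate" %in% stages) {
    for (tx in names(sim$genomes))
      write_genome(sim$genomes[[tx]], outdir)
    write_bed(sim$repeats, file.path(outdir, "repeats.bed"))
    write_truth_table(sim$truth, file.path(outdir, "truth.tsv"))
    write_config(config, file.path(outdir, "config.yaml"))
  }
  bp <- config$breakpoints
  analysis <- analyze_pair(sim$genomes$subobscura, sim$genomes$guanche,
                           outgroup = sim$genomes$outgroup,
                           min_anchors = config$synteny$min_anchors,
                           max_gap = config$synteny$max_gap,
                           flank_width = bp$flank_width,
                           min_dup_len = bp$min_dup_len,
                           min_identity = bp$min_identity,
                           tol = bp$tol, min_score = bp$min_score)
  res$analysis <- analysis
  if ("synteny" %in% stages) {
    write_tsv(as.data.frame(analysis$blocks),
              file.path(outdir, "synteny_blocks.tsv"), meta = meta)
    st <- analysis$stats
    write_tsv(data.frame(n_blocks = st$n_blocks,
                         mean_size_mb = st$mean_size_mb,
                         n_inverted = st$n_inverted),
              file.path(outdir, "block_stats.tsv"), meta = meta)
  }
  if ("breakpoints" %in% stages && nrow(analysis$calls))
    write_tsv(analysis$calls, file.path(outdir, "inversion_calls.tsv"),
              meta = meta)
  hist_res <- run_history(analysis, sim, config)
  res$history <- hist_res
  if ("history" %in% stages) {
    write_tsv(hist_res$branches, file.path(outdir, "branch_table.tsv"),
              meta = meta)
    write_tsv(hist_res$rates, file.path(outdir, "fixation_rates.tsv"),
              meta = meta)
  }
  if ("stats" %in% stages) {
    stats_res <- run_stats(sim, config)
    res$stats <- stats_res
    write_tsv(stats_res$gene_gtest, file.path(outdir, "gene_count_gtest.tsv"),
              meta = meta)
    write_tsv(stats_res$microsat_gradient,
              file.path(outdir, "microsat_gradient.tsv"), meta = meta)
  }
  if ("report" %in% stages) {
    rep <- collate_report(analysis, hist_res)
    res$report <- rep
    write_tsv(rep, file.path(outdir, "report.tsv"), meta = meta)
  }
  invisible(res)
}

# Tip arrangement states for each isolated call, from marker orders: a tip
# carries the derived state iff its order of the inverted block's markers
# matches the derived taxon's (forward or reversed); a tip with a distinct
# ancestral haplotype that lacks it is polymorphic.
call_tip_states <- function(analysis, sim) {
  taxa <- setdiff(names(sim$genomes), "outgroup")
  calls <- analysis$calls
  if (is.null(calls) || !nrow(calls)) return(NULL)
  blocks <- analysis$blocks
  out <- list()
  for (j in seq_len(nrow(calls))) {
    b <- blocks[blocks$block_id == calls$block_id[j], , drop = FALSE]
    ref_ch <- get_chrom(sim$genomes[[analysis$taxa[["ref"]]]], b$chrom1)
    m <- ref_ch$markers
    ids <- m$id[m$start >= b$start1 & m$end <= b$end1]
    derived <- calls$derived_taxon[j]
    if (is.na(derived)) next
    # the derived order of a single inversion is the exact reverse of the
    # ancestral order, so matching must be strict (genomes share one
    # coordinate orientation here)
    dord <- order_in(get_chrom(sim$genomes[[derived]], b$chrom1), ids)
    for (tx in taxa) {
      tord <- order_in(get_chrom(sim$genomes[[tx]], b$chrom1), ids)
      carries <- identical(tord, dord)
      state <- if (!carries) "absent" else "fixed"
      if (carries && !is.null(sim$haplotypes[[tx]])) {
        hord <- order_in(get_chrom(sim$haplotypes[[tx]], b$chrom1), ids)
        if (!identical(hord, dord)) state <- "polymorphic"
      }
      out[[length(out) + 1L]] <- data.frame(
        inversion_id = calls$inversion_id[j], taxon = tx, state = state,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Tip states for the hypothetical steps of each overlapping-inversion
# region: a tip carries the region's derived configuration iff its marker
# order over the region matches the derived taxon's; each of the
# `distance` scenario steps is recorded as one event on that background.
region_tip_states <- function(analysis, sim) {
  taxa <- setdiff(names(sim$genomes), "outgroup")
  out <- list()
  for (ri in seq_along(analysis$regions)) {
    r <- analysis$regions[[ri]]
    if (r$distance == 0L) next
    ref_tax <- analysis$taxa[["ref"]]; alt_tax <- analysis$taxa[["alt"]]
    ref_ch <- get_chrom(sim$genomes[[ref_tax]], r$chrom)
    m <- ref_ch$markers
    ids <- m$id[m$start >= r$start1 & m$end <= r$end1]
    oord <- order_in(get_chrom(sim$genomes$outgroup, r$chrom), ids)
    rord <- order_in(ref_ch, ids)
    aord <- order_in(get_chrom(sim$genomes[[alt_tax]], r$chrom), ids)
    derived <- if (!identical(rord, oord)) ref_tax
    else if (!identical(aord, oord)) alt_tax
    else next
    dord <- if (derived == ref_tax) rord else aord
    for (k in seq_len(r$distance)) {
      inv_id <- sprintf("%s_region%d_h%d", r$chrom, ri, k)
      for (tx in taxa) {
        tord <- order_in(get_chrom(sim$genomes[[tx]], r$chrom), ids)
        carries <- identical(tord, dord)
        state <- if (!carries) "absent" else "fixed"
        if (carries && !is.null(sim$haplotypes[[tx]])) {
          hord <- order_in(get_chrom(sim$haplotypes[[tx]], r$chrom), ids)
          if (!identical(hord, dord)) state <- "polymorphic"
        }
        out[[length(out) + 1L]] <- data.frame(
          inversion_id = inv_id, taxon = tx, state = state,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' History stage: branch assignment and fixation-rate comparisons
#'
#' Builds per-tip arrangement states for every isolated inversion call,
#' maps each inversion onto the species tree by single-origin parsimony,
#' and compares fixation rates: sex chromosome A versus the average large
#' autosome on the continental lineage, and the continental versus the
#' average island lineage.
#'
#' @param analysis An `inversion_analysis`.
#' @param sim A [simulate_template()] result.
#' @param config A [default_config()].
#' @return List with `tip_states`, `branches`, `rates` and the two
#'   `rate_comparison` objects.
#' @export
run_history <- function(analysis, sim, config = default_config()) {
  ts <- rbind(call_tip_states(analysis, sim),
              region_tip_states(analysis, sim))
  tree <- sim$tree
  branches <- if (!is.null(ts)) assign_to_branches(ts, tree) else NULL
  t_cont <- config$tree$age_subgroup
  t_island <- config$tree$age_subgroup + config$tree$age_ms_split
  rates <- NULL; cmp_A <- NULL; cmp_lineage <- NULL
  if (!is.null(branches)) {
    # fixed on the continental lineage = assigned to the subobscura branch
    # or its ancestor branch 'ms', with subobscura state fixed
    cont <- branches$branch %in% c("subobscura", "ms") &
      branches$state_subobscura == "fixed"
    isA <- grepl("^A", branches$inversion_id)
    autosomes <- c("J", "U", "E", "O")
    k_A <- sum(cont & isA)
    k_auto <- sum(cont & !isA)
    k_island <- sum(branches$branch %in% c("guanche", "madeirensis"))
    cmp_A <- rate_ratio_test(k_A, t_cont, k_auto,
                             length(autosomes) * t_cont)
    k_cont_all <- sum(cont)
    cmp_lineage <- rate_ratio_test(k_cont_all, t_cont, k_island, t_island)
    rates <- data.frame(
      comparison = c("A_vs_autosomes", "continental_vs_island"),
      k1 = c(cmp_A$k1, cmp_lineage$k1), t1 = c(cmp_A$t1, cmp_lineage$t1),
      rate1 = signif(c(cmp_A$rate1, cmp_lineage$rate1), 2),
      k2 = c(cmp_A$k2, cmp_lineage$k2), t2 = c(cmp_A$t2, cmp_lineage$t2),
      rate2 = signif(c(cmp_A$rate2, cmp_lineage$rate2), 2),
      ratio = signif(c(cmp_A$ratio, cmp_lineage$ratio), 2),
      p_two_sided = c(cmp_A$p_two_sided, cmp_lineage$p_two_sided),
      stringsAsFactors = FALSE)
  }
  list(tip_states = ts, branches = branches, rates = rates,
       cmp_A = cmp_A, cmp_lineage = cmp_lineage)
}

#' Distributional statistics stage
#'
#' G-test of simulated marker counts against chromosome lengths, and the
#' telomere-ward microsatellite density gradient per chromosome (windowed
#' density regression).
#'
#' @param sim A [simulate_template()] result.
#' @param config A [default_config()].
#' @return List with `gene_gtest` and `microsat_gradient` data.frames.
#' @export
run_stats <- function(sim, config = default_config()) {
  g <- sim$genomes$subobscura
  counts <- vapply(g$chromosomes, function(ch) nrow(ch$markers), 0L)
  lens <- vapply(g$chromosomes, `[[`, 0L, "length")
  gt <- g_test(counts, lens, categories = chrom_names(g))
  gt_df <- data.frame(G = gt$G, df = gt$df, p = gt$p)
  ms <- sim$repeats[sim$repeats$name == "microsatellite", , drop = FALSE]
  grad <- list()
  for (chr in setdiff(chrom_names(g), "dot")) {
    r <- ms[ms$chrom == chr, , drop = FALSE]
    L <- get_chrom(g, chr)$length
    wp <- window_density(r, L, window = config$stats$window,
                         step = config$stats$step)
    fit <- linreg_density(wp$windows$mid, wp$density)
    grad[[length(grad) + 1L]] <- data.frame(
      chrom = chr, slope = fit$slope, r2 = fit$r2, p = fit$p,
      stringsAsFactors = FALSE)
  }
  list(gene_gtest = gt_df, microsat_gradient = do.call(rbind, grad))
}

# Collated report: one row per isolated inversion call plus one row per
# hypothetical step of each complex-region reversal scenario.
collate_report <- function(analysis, hist_res) {
  rows <- list()
  calls <- analysis$calls
  if (!is.null(calls) && nrow(calls)) {
    br <- hist_res$branches
    for (j in seq_len(nrow(calls))) {
      branch <- if (!is.null(br)) {
        i <- match(calls$inversion_id[j], br$inversion_id)
        if (is.na(i)) NA_character_ else br$branch[i]
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        id = calls$inversion_id[j], chrom = calls$chrom[j],
        kind = "isolated",
        prox_start = calls$ref_prox_start[j],
        prox_end = calls$ref_prox_end[j],
        dist_start = calls$ref_dist_start[j],
        dist_end = calls$ref_dist_end[j],
        mechanism = calls$mechanism[j],
        dup_len = ifelse(is.na(calls$derived_taxon[j]) |
                           calls$derived_taxon[j] == analysis$taxa[["ref"]],
                         calls$dup_len_ref[j], calls$dup_len_alt[j]),
        derived_taxon = calls$derived_taxon[j],
        branch = branch,
        reciprocal_ok = calls$reciprocal_ok[j],
        gene_disrupted = calls$gene_disrupted[j],
        stringsAsFactors = FALSE)
    }
  }
  br <- hist_res$branches
  for (ri in seq_along(analysis$regions)) {
    r <- analysis$regions[[ri]]
    for (s in seq_along(r$scenario$reversals)) {
      id <- sprintf("%s_region%d_h%d", r$chrom, ri, s)
      branch <- if (!is.null(br) && id %in% br$inversion_id)
        br$branch[match(id, br$inversion_id)] else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, chrom = r$chrom,
        kind = "scenario_step",
        prox_start = r$start1, prox_end = r$start1,
        dist_start = r$end1, dist_end = r$end1,
        mechanism = NA_character_, dup_len = NA_integer_,
        derived_taxon = NA_character_, branch = branch,
        reciprocal_ok = NA, gene_disrupted = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}
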