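# Command-line pipeline: subcommand dispatcher, TSV artifacts, run manifest.

.cli_log <- function(verbosity, level, ...) {
  if (verbosity >= level) message("[rcug] ", ...)
}

# parse "--key value" pairs (plus bare -v/-vv) into a named list; values from
# an optional "key = value" config file are applied first, flags override
.parse_cli_args <- function(args) {
  opts <- list(verbosity = 0L)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("-v", "-vv")) {
      opts$verbosity <- if (a == "-vv") 2L else max(opts$verbosity, 1L)
      i <- i + 1
    } else if (grepl("^--[A-Za-z]", a)) {
      key <- gsub("-", "_", sub("^--", "", a))
      if (i == length(args) || grepl("^--", args[i + 1]))
        stop("usage error: flag ", a, " needs a value")
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      stop("usage error: unexpected argument '", a, "'")
    }
  }
  if (!is.null(opts$config)) {
    if (!file.exists(opts$config))
      stop("config file not found: ", opts$config)
    for (line in readLines(opts$config)) {
      line <- sub("#.*", "", line)
      if (!grepl("=", line)) next
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      key <- gsub("-", "_", trimws(kv[1]))
      if (is.null(opts[[key]])) opts[[key]] <- trimws(paste(kv[-1],
                                                           collapse = "="))
    }
  }
  opts
}

.opt <- function(opts, key, default = NULL, as = identity) {
  v <- opts[[key]]
  if (is.null(v)) default else as(v)
}

.opt_int <- function(opts, key, default) .opt(opts, key, default, as.integer)
.opt_num <- function(opts, key, default) .opt(opts, key, default, as.numeric)

# "5:15" or "5,7,9" -> numeric vector
.parse_range <- function(s) {
  if (grepl(":", s)) {
    ab <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    seq(ab[1], ab[2])
  } else as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
}

# TSV with a '#'-comment header carrying the run parameters
.write_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(paste0("# ", k, " = ", paste(params[[k]], collapse = " ")), con)
  utils::write.table(format(df, trim = TRUE, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

.mode_table <- function(modes, k) {
  k <- min(k, ncol(modes$vectors))
  tab <- as.data.frame(modes$vectors[, seq_len(k), drop = FALSE])
  names(tab) <- paste0(tolower(modes$kind), seq_len(k))
  if (!is.null(modes$labels)) {
    lab <- modes$labels[rep(seq_len(nrow(modes$labels)), each = 3), ]
    lab$axis <- rep(c("x", "y", "z"), nrow(modes$labels))
    tab <- cbind(lab, tab)
  }
  tab
}

.read_single_structure <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  read_rna_pdb(path)[[1]]
}

.read_node_ensemble <- function(path, scheme) {
  if (!file.exists(path)) stop("ensemble file not found: ", path)
  frames <- read_rna_pdb(path)
  ensemble_from_structures(frames, scheme, source = path)
}

.cli_manifest <- function(out_dir, subcommand, params, inputs, outputs) {
  manifest <- list(
    tool = "rcug-tools", subcommand = subcommand,
    parameters = params,
    inputs = lapply(inputs[file.exists(unlist(inputs))], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  path <- file.path(out_dir, paste0(subcommand, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Command-line pipeline entry point
#'
#' Dispatches one subcommand of the `rcug-tools` pipeline. Every subcommand
#' writes plain-text TSV and/or PDB artifacts into `--out-dir` plus a JSON
#' manifest recording parameters and input/output MD5 checksums; outputs are
#' deterministic for a fixed `--seed`. Flags are `--key value` pairs (an
#' optional `--config file` of `key = value` lines supplies defaults;
#' explicit flags win). `-v`/`-vv` raise logging verbosity on standard error.
#'
#' Subcommands:
#' * `synth`: build an idealized duplex (`--repeats`, `--cap`) or, with
#'   `--kind trajectory`, a Gaussian synthetic trajectory (`--n-frames`,
#'   `--drift`, `--total-variance`).
#' * `build-ensemble`: read a multi-model PDB, optionally cut (CUG)n
#'   fragments (`--fragments yes --repeats n --stride s`), select scheme
#'   nodes, iteratively align, and write the aligned node ensemble.
#' * `pca` / `eda`: principal components of an ensemble file (`eda` first
#'   subsamples `--n-frames` equally spaced frames); writes spectrum, mode
#'   vectors and RMSF profiles.
#' * `anm`: ANM eigenvalues, soft-mode vectors and collectivities for a
#'   structure (`--scheme`, `--cutoff`, `--law`, `--gamma0`).
#' * `compare`: overlap table, cumulative overlaps, subspace overlap and
#'   RMSF correlation between an ensemble's PCA and a structure's ANM.
#' * `scan`: cutoff/scheme/law grid of best soft-mode-vs-PC1 overlaps.
#' * `conformers`: sample an ANM-conformer ensemble PDB from a structure.
#' * `projections`: project an ensemble onto another ensemble's top PCs.
#' * `classify-uu`: U-U pair classification table for a structure.
#' * `cluster-uu`: average-linkage clustering of one U-U pair across
#'   trajectory frames (`--pair`, `--threshold`).
#'
#' @param args character vector of command-line arguments (subcommand first).
#' @return (Invisibly) the list of artifact paths written. Errors propagate
#'   as normal R errors; the installed `rcug-tools.R` script converts them to
#'   a nonzero exit status.
#' @export
rcug_cli <- function(args) {
  if (length(args) == 0)
    stop("usage: rcug-tools <subcommand> [--key value ...]; subcommands: ",
         "synth build-ensemble pca eda anm compare scan conformers ",
         "projections classify-uu cluster-uu")
  sub <- args[1]
  opts <- .parse_cli_args(args[-1])
  out_dir <- .opt(opts, "out_dir", ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- .opt_int(opts, "seed", 1L)
  vb <- opts$verbosity
  scheme_name <- .opt(opts, "scheme", "CG2")
  outputs <- character(0)
  inputs <- character(0)
  params <- opts[setdiff(names(opts), "verbosity")]
  params$seed <- seed

  if (sub == "synth") {
    kind <- .opt(opts, "kind", "duplex")
    reps <- .opt_int(opts, "repeats", 3L)
    cap <- .opt(opts, "cap", "GC")
    duplex <- build_cug_duplex(reps, cap = cap)
    if (kind == "duplex") {
      p <- file.path(out_dir, "duplex.pdb")
      write_rna_pdb(duplex, p)
      outputs <- p
    } else if (kind == "trajectory") {
      nodes <- select_nodes(duplex, cg_scheme(scheme_name))
      gm <- model_from_fractions(
        nodes, total_variance = .opt_num(opts, "total_variance", 50),
        seed = seed)
      p <- file.path(out_dir, "trajectory.pdb")
      synthetic_trajectory(gm, p, n_frames = .opt_int(opts, "n_frames", 200L),
                           seed = seed,
                           drift_amplitude = .opt_num(opts, "drift", 0))
      outputs <- p
    } else stop("usage error: unknown synth kind '", kind, "'")
    .cli_log(vb, 1, "synth ", kind, " written to ", outputs)

  } else if (sub == "build-ensemble") {
    input <- .opt(opts, "input")
    if (is.null(input)) stop("usage error: build-ensemble needs --input")
    inputs <- input
    if (!file.exists(input)) stop("input file not found: ", input)
    structures <- read_rna_pdb(input)
    if (identical(.opt(opts, "fragments", "no"), "yes")) {
      structures <- unlist(lapply(structures, extract_cug_fragments,
                                  n_repeats = .opt_int(opts, "repeats", 3L),
                                  stride = .opt_int(opts, "stride", 1L)),
                           recursive = FALSE)
      .cli_log(vb, 1, length(structures), " fragments extracted")
      if (length(structures) == 0) stop("no (CUG)n fragments found in ", input)
    }
    ens <- ensemble_from_structures(structures, cg_scheme(scheme_name),
                                    source = input)
    p <- file.path(out_dir, "ensemble.pdb")
    write_rna_pdb(ens, p)
    outputs <- p
    .cli_log(vb, 1, "aligned ensemble: ", n_conformers(ens), " x ",
             n_nodes(ens), " nodes")

  } else if (sub %in% c("pca", "eda")) {
    input <- .opt(opts, "ensemble")
    if (is.null(input)) stop("usage error: ", sub, " needs --ensemble")
    inputs <- input
    ens <- .read_node_ensemble(input, cg_scheme(scheme_name))
    if (sub == "eda")
      ens <- subsample_frames(ens, n = .opt_int(opts, "n_frames", 2000L))
    pc <- pca_modes(ens)
    k <- .opt_int(opts, "n_modes", 3L)
    outputs <- c(
      .write_tsv(pc$spectrum, file.path(out_dir, paste0(sub, "_spectrum.tsv")),
                 params),
      .write_tsv(.mode_table(pc$modes, k),
                 file.path(out_dir, paste0(sub, "_modes.tsv")), params),
      .write_tsv(rmsf_profile(ens),
                 file.path(out_dir, paste0(sub, "_rmsf.tsv")), params))
    .cli_log(vb, 1, sub, ": ", length(pc$modes$values), " components, PC1 ",
             round(100 * pc$spectrum$fraction[1], 1), "% of variance")

  } else if (sub == "anm") {
    input <- .opt(opts, "input")
    if (is.null(input)) stop("usage error: anm needs --input")
    inputs <- input
    nodes <- select_nodes(.read_single_structure(input),
                          cg_scheme(scheme_name))
    fc <- force_constant(.opt(opts, "law", "exponential"),
                         gamma0 = .opt_num(opts, "gamma0", 12),
                         cutoff = .opt_num(opts, "cutoff", 9))
    md <- solve_modes(build_hessian(nodes, fc))
    k <- .opt_int(opts, "n_modes", 6L)
    spec <- data.frame(mode = seq_along(md$values), lambda = md$values)
    spec$collectivity <- apply(md$vectors, 2, collectivity)
    outputs <- c(
      .write_tsv(spec, file.path(out_dir, "anm_spectrum.tsv"), params),
      .write_tsv(.mode_table(md, k), file.path(out_dir, "anm_modes.tsv"),
                 params))
    .cli_log(vb, 1, "anm: ", length(md$values), " modes, softest lambda ",
             signif(md$values[1], 4))

  } else if (sub == "compare") {
    ens_path <- .opt(opts, "ensemble"); ref_path <- .opt(opts, "input")
    if (is.null(ens_path) || is.null(ref_path))
      stop("usage error: compare needs --ensemble and --input")
    inputs <- c(ens_path, ref_path)
    scheme <- cg_scheme(scheme_name)
    ens <- .read_node_ensemble(ens_path, scheme)
    nodes <- select_nodes(.read_single_structure(ref_path), scheme)
    fc <- force_constant(.opt(opts, "law", "exponential"),
                         gamma0 = .opt_num(opts, "gamma0", 12),
                         cutoff = .opt_num(opts, "cutoff", 9))
    md <- solve_modes(build_hessian(nodes, fc))
    pc <- pca_modes(ens)
    kA <- .opt_int(opts, "n_modes", 6L)
    ot <- overlap_table(pc$modes, md, kA = kA, kB = kA)
    ov_df <- data.frame(pc = rep(rownames(ot), ncol(ot)),
                        anm = rep(colnames(ot), each = nrow(ot)),
                        overlap = as.numeric(ot))
    K <- .opt_int(opts, "subspace_k", 3L)
    co <- vapply(seq_len(min(3, ncol(pc$modes$vectors))), function(j)
      cumulative_overlap(pc$modes$vectors[, j], md,
                         J = .opt_int(opts, "co_j", 20L)), numeric(1))
    summ <- data.frame(
      metric = c(paste0("cumulative_overlap_pc", seq_along(co)),
                 paste0("subspace_overlap_k", K), "rmsf_correlation"),
      value = c(co, subspace_overlap(pc$modes, md, K = K),
                fluctuation_correlation(
                  rmsf_profile(ens)$rmsf,
                  sqrt(rowSums(matrix(diag(anm_covariance(md)),
                                      ncol = 3, byrow = TRUE))))))
    outputs <- c(
      .write_tsv(ov_df, file.path(out_dir, "compare_overlaps.tsv"), params),
      .write_tsv(summ, file.path(out_dir, "compare_summary.tsv"), params))
    .cli_log(vb, 1, "compare: max overlap ", round(max(ot), 3))

  } else if (sub == "scan") {
    ens_path <- .opt(opts, "ensemble"); ref_path <- .opt(opts, "input")
    if (is.null(ens_path) || is.null(ref_path))
      stop("usage error: scan needs --ensemble and --input")
    inputs <- c(ens_path, ref_path)
    schemes <- strsplit(.opt(opts, "schemes", scheme_name), ",")[[1]]
    ref <- .read_single_structure(ref_path)
    pcs <- stats::setNames(lapply(schemes, function(sc)
      pca_modes(.read_node_ensemble(ens_path, cg_scheme(sc)))), schemes)
    res <- scan_parameters(
      pcs, ref, schemes = schemes,
      cutoffs = .parse_range(.opt(opts, "cutoffs", "5:15")),
      laws = strsplit(.opt(opts, "laws", "exponential"), ",")[[1]],
      n_soft = .opt_int(opts, "n_soft", 6L),
      gamma0 = .opt_num(opts, "gamma0", 12))
    outputs <- .write_tsv(res$grid, file.path(out_dir, "scan_grid.tsv"),
                          params)
    .cli_log(vb, 1, "scan best: ", res$best$scheme, " ", res$best$cutoff,
             " A ", res$best$law, " overlap ", round(res$best$best_overlap, 3))

  } else if (sub == "conformers") {
    input <- .opt(opts, "input")
    if (is.null(input)) stop("usage error: conformers needs --input")
    inputs <- input
    nodes <- select_nodes(.read_single_structure(input),
                          cg_scheme(scheme_name))
    fc <- force_constant(.opt(opts, "law", "exponential"),
                         gamma0 = .opt_num(opts, "gamma0", 12),
                         cutoff = .opt_num(opts, "cutoff", 9))
    md <- solve_modes(build_hessian(nodes, fc))
    n_modes <- .opt_int(opts, "n_soft", 3L)
    ens <- sample_conformers(nodes, md, mode_indices = seq_len(n_modes),
                             n = .opt_int(opts, "n", 2000L),
                             target_rmsd = .opt_num(opts, "target_rmsd", 2.0),
                             seed = seed)
    p <- file.path(out_dir, "conformers.pdb")
    write_rna_pdb(ens, p)
    outputs <- p
    .cli_log(vb, 1, "conformers: ", n_conformers(ens), " sampled")

  } else if (sub == "projections") {
    ens_path <- .opt(opts, "ensemble"); other_path <- .opt(opts, "other")
    if (is.null(ens_path) || is.null(other_path))
      stop("usage error: projections needs --ensemble and --other")
    inputs <- c(ens_path, other_path)
    scheme <- cg_scheme(scheme_name)
    pc <- pca_modes(.read_node_ensemble(ens_path, scheme))
    other <- .read_node_ensemble(other_path, scheme)
    proj <- project_ensemble(other, pc, k = .opt_int(opts, "n_modes", 3L))
    df <- cbind(data.frame(conformer = seq_len(nrow(proj))),
                as.data.frame(proj))
    outputs <- .write_tsv(df, file.path(out_dir, "projections.tsv"), params)
    .cli_log(vb, 1, "projections: ", nrow(proj), " conformers x ",
             ncol(proj), " components")

  } else if (sub == "classify-uu") {
    input <- .opt(opts, "input")
    if (is.null(input)) stop("usage error: classify-uu needs --input")
    inputs <- input
    tab <- classify_uu_table(.read_single_structure(input),
                             dist_cutoff = .opt_num(opts, "dist_cutoff", 3.5))
    outputs <- .write_tsv(tab, file.path(out_dir, "uu_classes.tsv"), params)
    .cli_log(vb, 1, "classify-uu: ", nrow(tab), " pair(s)")

  } else if (sub == "cluster-uu") {
    input <- .opt(opts, "input")
    if (is.null(input)) stop("usage error: cluster-uu needs --input")
    inputs <- input
    if (!file.exists(input)) stop("input file not found: ", input)
    frames <- read_rna_pdb(input)
    cl <- cluster_uu_trajectory(frames,
                                pair_index = .opt_int(opts, "pair", 1L),
                                threshold = .opt_num(opts, "threshold", 3.0))
    outputs <- c(
      .write_tsv(data.frame(frame = seq_along(cl$labels),
                            cluster = cl$labels),
                 file.path(out_dir, "uu_cluster_labels.tsv"), params),
      .write_tsv(cl$populations,
                 file.path(out_dir, "uu_cluster_populations.tsv"), params))
    .cli_log(vb, 1, "cluster-uu: ", nrow(cl$populations), " cluster(s)")

  } else {
    stop("usage error: unknown subcommand '", sub, "'")
  }

  outputs <- c(outputs,
               .cli_manifest(out_dir, sub, params, inputs, outputs))
  invisible(outputs)
}
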