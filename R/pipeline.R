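pipeline_defaults <- function() {
  list(reads_manifest = "", db_fasta = "", out_dir = "",
       stages = "build_db,prescreen,em,abundance,diversity,stats",
       max_iters = 40L, threads = 1L, snp_fraction = 0.04,
       variant_fraction = 0.1, join_identity = 0.97, min_depth = 3,
       phred_offset = 33L, seed = 1L, max_error_rate = 0.15,
       prescreen = TRUE, kmer = 21L, min_shared = 1L,
       min_length = 150L, cluster_identity = 0.97,
       tree_file = "", env_file = "", mantel_perm = 999L,
       fractional = FALSE)
}

# short flags accepted as aliases for the long keys
pipeline_aliases <- c(n = "max_iters", a = "threads", p = "snp_fraction",
                      v = "variant_fraction", j = "join_identity",
                      c = "min_depth", phred = "phred_offset",
                      k = "kmer")

#' Read a plain-text pipeline configuration
#'
#' `key = value` lines; `#` starts a comment.  Short aliases `n, a, p, v, j,
#' c, phred, k` map to the long parameter names.  Missing keys take the
#' defaults (40 iterations, split fraction 0.04, variant fraction 0.1, join
#' identity 0.97, minimum depth 3, Phred+33).
#'
#' @param path Path to the config file.
#' @return Named list of parameters (strings not yet validated; see
#'   [validate_config()]).
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && !all(grepl("=", lines, fixed = TRUE)))
    stop("unparseable config line: ", lines[!grepl("=", lines)][1L])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  cfg <- stats::setNames(as.list(vals), keys)
  fill_config(cfg)
}

fill_config <- function(cfg) {
  defaults <- pipeline_defaults()
  out <- defaults
  extra <- character(0)
  for (k in names(cfg)) {
    key <- if (k %in% names(pipeline_aliases)) pipeline_aliases[[k]] else k
    if (!key %in% names(defaults)) { extra <- c(extra, k); next }
    v <- cfg[[k]]
    out[[key]] <- switch(class(defaults[[key]])[1],
                         integer = as.integer(v),
                         numeric = as.numeric(v),
                         logical = as.logical(v),
                         as.character(v))
  }
  attr(out, "unknown_keys") <- extra
  out
}

#' Validate a pipeline configuration
#'
#' @param config Named list (possibly partial; defaults are filled in) or a
#'   config file path.
#' @return Character vector of violations; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  if (is.null(attr(config, "unknown_keys"))) config <- fill_config(config)
  v <- character(0)
  for (k in attr(config, "unknown_keys"))
    v <- c(v, sprintf("unknown key '%s'", k))
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  for (f in c("snp_fraction", "variant_fraction", "join_identity",
              "cluster_identity"))
    chk(is.finite(config[[f]]) && config[[f]] > 0 && config[[f]] < 1,
        sprintf("%s must lie in (0, 1), got %s", f, config[[f]]))
  chk(!is.na(config$max_iters) && config$max_iters >= 1L,
      "max_iters must be >= 1")
  chk(!is.na(config$threads) && config$threads >= 1L, "threads must be >= 1")
  chk(is.finite(config$min_depth) && config$min_depth >= 0,
      "min_depth must be >= 0")
  chk(config$phred_offset %in% c(33L, 64L), "phred_offset must be 33 or 64")
  chk(is.finite(config$max_error_rate) && config$max_error_rate > 0 &&
        config$max_error_rate < 1, "max_error_rate must lie in (0, 1)")
  chk(!is.na(config$kmer) && config$kmer >= 4L, "kmer must be >= 4")
  chk(!is.na(config$min_shared) && config$min_shared >= 1L,
      "min_shared must be >= 1")
  chk(!is.na(config$min_length) && config$min_length >= 1L,
      "min_length must be >= 1")
  chk(!is.na(config$mantel_perm) && config$mantel_perm >= 1L,
      "mantel_perm must be >= 1")
  stages <- strsplit(config$stages, ",")[[1]]
  known <- c("build_db", "prescreen", "em", "abundance", "diversity", "stats")
  for (s in setdiff(trimws(stages), known))
    v <- c(v, sprintf("unknown stage '%s'", s))
  if (nzchar(config$reads_manifest))
    chk(file.exists(config$reads_manifest),
        sprintf("reads_manifest not found: %s", config$reads_manifest))
  if (nzchar(config$db_fasta))
    chk(file.exists(config$db_fasta),
        sprintf("db_fasta not found: %s", config$db_fasta))
  if (nzchar(config$tree_file))
    chk(file.exists(config$tree_file),
        sprintf("tree_file not found: %s", config$tree_file))
  v
}

#' Relabel a reference tree with reconstructed cluster ids
#'
#' A gene tree is usually built over the starting-database sequences; this
#' helper renames each tip carrying a source (representative) id to the
#' cluster reconstructed from it, so the tree can be used with cluster
#' abundance tables.  A source with several clusters (splits) becomes a
#' zero-branch-length polytomy of its cluster ids; source tips without any
#' reconstructed cluster are dropped.  Tips already labeled by cluster ids
#' are kept as-is.
#'
#' @param tree An [ape::phylo] tree or newick string.
#' @param fit A `gscem` fit.
#' @return The relabeled tree.
#' @export
relabel_tree_for_gscs <- function(tree, fit) {
  if (is.character(tree)) tree <- parse_newick(tree)
  g <- fit$gscs
  # follow each cluster's source chain to its db-origin representative
  src <- vapply(seq_len(nrow(g)), function(i) {
    cur <- i
    while (g$origin[cur] != "db") {
      nxt <- match(g$source_id[cur], g$id)
      if (is.na(nxt)) break
      cur <- nxt
    }
    g$source_id[cur]
  }, character(1))
  txt <- ape::write.tree(tree)
  matched <- logical(nrow(g))
  for (tip in tree$tip.label) {
    if (tip %in% g$id) { matched[g$id == tip] <- TRUE; next }
    hits <- which(src == tip & !g$id %in% tree$tip.label)
    if (!length(hits)) {
      tree2 <- parse_newick(txt)
      tree2 <- ape::drop.tip(tree2, tip)
      if (is.null(tree2)) stop("no reconstructed cluster matches the tree")
      txt <- ape::write.tree(tree2)
      next
    }
    matched[hits] <- TRUE
    repl <- if (length(hits) == 1L) g$id[hits]
      else sprintf("(%s)", paste0(g$id[hits], ":0", collapse = ","))
    txt <- gsub(sprintf("([(,])%s:", tip), sprintf("\\1%s:", repl), txt)
    txt <- gsub(sprintf("([(,])%s([,)])", tip),
                sprintf("\\1%s\\2", repl), txt)
  }
  if (!all(matched))
    stop("cluster source not present in the tree: ",
         g$source_id[!matched][1L])
  parse_newick(txt)
}

#' Run the full reconstruction pipeline from a config
#'
#' Chains database construction, read pre-screening, the EM reconstruction,
#' per-sample abundance counting and normalization, diversity profiling
#' (Hill numbers, weighted UniFrac, MNTD against a supplied gene tree) and
#' ordination/correlation statistics (PCoA; Mantel against an environmental
#' table).  Stages absent from `stages` are skipped.  A `manifest.tsv`
#' records every output file with its MD5 checksum, and `config_used.tsv`
#' snapshots the effective parameters; rerunning with an identical config
#' reproduces identical checksums.  Timestamped progress goes to `run.log`.
#'
#' @param config Config file path or named list (see
#'   [read_pipeline_config()]).
#' @return The output directory path, invisibly; the fitted `gscem` object
#'   is attached as attribute `"fit"` when the em stage ran.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  else config <- fill_config(config)
  violations <- validate_config(config)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  if (!nzchar(config$out_dir)) stop("out_dir is required")
  if (!nzchar(config$reads_manifest)) stop("reads_manifest is required")
  if (!nzchar(config$db_fasta)) stop("db_fasta is required")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  cat("", file = logf)
  logmsg <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                              sprintf(...), "\n", sep = "", file = logf,
                              append = TRUE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0))
  record <- function(stage, files) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files))))
  }
  stages <- trimws(strsplit(config$stages, ",")[[1]])

  # snapshot records parameters, not the output location
  snap <- config[setdiff(sort(names(config)), "out_dir")]
  utils::write.table(
    data.frame(key = names(snap),
               value = vapply(snap, function(x) paste(x, collapse = ","),
                              character(1))),
    file.path(out, "config_used.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  record("config", file.path(out, "config_used.tsv"))

  man <- utils::read.delim(config$reads_manifest, stringsAsFactors = FALSE)
  reads <- do.call(rbind, lapply(seq_len(nrow(man)), function(i)
    read_fastq_pair(man$r1[i], man$r2[i],
                    phred_offset = config$phred_offset)))
  # pairs must be unique across samples
  reads$pair <- match(reads$id, unique(reads$id))
  reads_per_sample <- table(reads$sample_tag)
  logmsg("loaded %d reads from %d samples", nrow(reads), nrow(man))

  db <- NULL; fit <- NULL
  if ("build_db" %in% stages) {
    db <- build_reference_db(config$db_fasta, config$min_length,
                             config$cluster_identity)
    write_reference_db(db, file.path(out, "db_representatives.fasta"),
                       file.path(out, "cluster_map.tsv"))
    record("build_db", file.path(out, c("db_representatives.fasta",
                                        "cluster_map.tsv")))
    logmsg("build_db: %d representatives", nrow(db$representatives))
  } else {
    db <- stats::setNames(read_fasta(config$db_fasta)$sequence,
                          read_fasta(config$db_fasta)$id)
  }

  if ("prescreen" %in% stages && isTRUE(config$prescreen)) {
    before <- nrow(reads)
    reads <- prescreen_reads(reads, db, config$kmer, config$min_shared)
    utils::write.table(
      data.frame(reads_in = before, reads_out = nrow(reads)),
      file.path(out, "prescreen_stats.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    record("prescreen", file.path(out, "prescreen_stats.tsv"))
    logmsg("prescreen: %d -> %d reads", before, nrow(reads))
  }

  if ("em" %in% stages) {
    emcfg <- gscem_config(
      max_iters = config$max_iters, threads = config$threads,
      snp_fraction = config$snp_fraction,
      variant_fraction = config$variant_fraction,
      join_identity = config$join_identity, min_depth = config$min_depth,
      phred_offset = config$phred_offset, seed = config$seed,
      max_error_rate = config$max_error_rate)
    fit <- gscem(reads, db, emcfg)
    write_gscem_outputs(fit, out)
    record("em", file.path(out, c("gscs.fasta", "relative_abundance.tsv",
                                  "final.sam", "iterations.tsv")))
    logmsg("em: %d GSCs, logLik %.3f", nrow(fit$gscs), fit$logLik)
  }

  A <- NULL; N <- NULL
  if ("abundance" %in% stages) {
    if (is.null(fit)) stop("abundance stage requires the em stage")
    A <- count_abundance(fit, samples = man$sample,
                         fractional = isTRUE(config$fractional))
    N <- normalize_abundance(A, reads_per_sample,
                             stats::setNames(fit$gscs$length, fit$gscs$id))
    write_abundance_tsv(A, file.path(out, "abundance_raw.tsv"))
    write_abundance_tsv(N, file.path(out, "abundance_norm.tsv"))
    record("abundance", file.path(out, c("abundance_raw.tsv",
                                         "abundance_norm.tsv")))
    logmsg("abundance: %d samples x %d GSCs", nrow(A), ncol(A))
  }

  D_uni <- NULL
  if ("diversity" %in% stages) {
    if (is.null(N)) stop("diversity stage requires the abundance stage")
    if (!nzchar(config$tree_file))
      stop("diversity stage requires a tree_file")
    tree <- relabel_tree_for_gscs(parse_newick(config$tree_file), fit)
    prof <- diversity_profiles(N, q = c(0, 1, 2), tree = tree)
    utils::write.table(prof, file.path(out, "diversity_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    D_uni <- unifrac_matrix(tree, N)
    write_abundance_tsv(D_uni, file.path(out, "unifrac.tsv"))
    mn <- vapply(rownames(N), function(s) {
      p <- stats::setNames(N[s, ], colnames(N))
      if (sum(p > 0) < 2L) NA_real_ else mntd(tree, p)
    }, numeric(1))
    utils::write.table(data.frame(sample = names(mn), mntd = unname(mn)),
                       file.path(out, "mntd.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("diversity", file.path(out, c("diversity_profiles.tsv",
                                         "unifrac.tsv", "mntd.tsv")))
    logmsg("diversity: profiles, unifrac, mntd done")
  }

  if ("stats" %in% stages) {
    if (is.null(D_uni)) stop("stats stage requires the diversity stage")
    ord <- pcoa(D_uni, k = min(2L, nrow(D_uni) - 1L))
    pc <- data.frame(sample = rownames(ord$coordinates), ord$coordinates)
    utils::write.table(pc, file.path(out, "pcoa.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- file.path(out, "pcoa.tsv")
    if (nzchar(config$env_file)) {
      env <- utils::read.delim(config$env_file, stringsAsFactors = FALSE)
      rownames(env) <- env$sample
      env <- env[rownames(D_uni), setdiff(names(env), "sample"),
                 drop = FALSE]
      D_env <- euclidean_distance(env)
      mt <- mantel_test(D_uni, D_env, n_perm = config$mantel_perm,
                        seed = derive_seed(config$seed, 4242L))
      utils::write.table(
        data.frame(r = mt$r, p_value = mt$p_value, n_perm = mt$n_perm),
        file.path(out, "mantel.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      files <- c(files, file.path(out, "mantel.tsv"))
    }
    record("stats", files)
    logmsg("stats: ordination%s done",
           if (nzchar(config$env_file)) " and Mantel" else "")
  }

  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logmsg("pipeline complete: %d stages", length(stages))
  invisible(structure(out, fit = fit))
}
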