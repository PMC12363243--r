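#' Run configuration
#'
#' Flat key = value run configuration for the pipeline and its command-line
#' front end. Unknown keys are rejected so that typos cannot silently fall
#' back to defaults.
#'
#' @param ... configuration values overriding the defaults.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    reads_dir = NULL, metadata = NULL, annotations_dir = NULL,
    out_dir = "tetraphase_out",
    k = 500, grid_resolution = 200, grid_margin = 0.05,
    pseudocount_policy = "add_one",
    lda_train_fraction = 0.8, rf_train_fraction = 0.75,
    seed = 1, shrink = 1e-3, num_trees = 500,
    overlay_gene = NULL, colormap_min = NA, colormap_max = NA,
    heat_midpoint = NA,
    plot_format = "svg", log_level = "info")
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all configuration values must be named")
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, over, keep.null = TRUE) |>
    structure(class = "run_config")
}

#' Read a key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values are coerced to numeric where possible.
#'
#' @param path configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3L))
    stop("malformed configuration line: ",
         lines[which(lengths(kv) != 3L)[1L]])
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3L])
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  do.call(run_config, setNames(vals, keys))
}

.log <- function(config, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

#' Run the full stability-diagram pipeline
#'
#' Chains every stage: read FASTA/FASTQ reads per metagenome, load and
#' filter metadata, count canonical tetranucleotides, build feature
#' vectors, fit the discriminant projection, evaluate the held-out split,
#' build the KNN phase grid and phase assignments, and — when annotations
#' are provided — the gene abundance table, per-gene group statistics for
#' the overlay gene, and random-forest importance rankings. All tabular
#' artifacts are written as TSV into `out_dir` together with a
#' `manifest.json` recording the configuration and seeds; the diagram is
#' rendered to SVG/PNG.
#'
#' Read files are matched to metadata by file name: `<sample_id>.fasta`,
#' `.fa`, `.fastq`, `.fq` (optionally `.gz`); annotation files as
#' `<sample_id>.gff3` / `.gff`.
#'
#' @param config a `run_config` (or arguments forwarded to [run_config()]).
#' @return invisible list with every intermediate object (`features`,
#'   `diagram`, `metrics`, `grid`, `phases`, `abundance`, `importance`,
#'   `paths`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  if (is.null(config$reads_dir) || is.null(config$metadata))
    stop("config needs at least 'reads_dir' and 'metadata'")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  .log(config, "info", "loading metadata: ", config$metadata)
  meta <- load_metadata(config$metadata)
  meta <- filter_metadata(meta)

  pats <- c(".fasta", ".fa", ".fastq", ".fq")
  pats <- c(pats, paste0(pats, ".gz"))
  find_reads <- function(sid) {
    for (p in pats) {
      f <- file.path(config$reads_dir, paste0(sid, p))
      if (file.exists(f)) return(f)
    }
    NA_character_
  }
  files <- vapply(meta$sample_id, find_reads, character(1))
  if (all(is.na(files))) stop("no read files found in ", config$reads_dir)
  if (any(is.na(files)))
    .log(config, "warn", sum(is.na(files)), " metadata sample(s) without ",
         "read files are dropped")
  meta <- meta[!is.na(files), , drop = FALSE]
  files <- files[!is.na(files)]

  .log(config, "info", "counting tetranucleotides in ", nrow(meta),
       " metagenomes")
  idx <- build_canonical_index()
  profiles <- lapply(seq_len(nrow(meta)), function(i)
    count_tetramers(read_sequences(files[[i]]), meta$sample_id[i], idx))
  feats <- suppressMessages(
    feature_matrix(profiles, config$pseudocount_policy))
  labels <- setNames(meta$group_key, meta$sample_id)[rownames(feats)]

  .log(config, "info", "fitting discriminant projection")
  diagram <- fit_lda(feats, labels, shrink = config$shrink)
  metrics <- evaluate_split(feats, labels,
                            train_fraction = config$lda_train_fraction,
                            seed = config$seed, shrink = config$shrink)
  grid <- build_phase_grid(diagram, k = config$k,
                           resolution = config$grid_resolution,
                           margin = config$grid_margin)
  phases <- assign_phases(diagram, grid)

  paths <- list(coordinates = file.path(out, "coordinates.tsv"),
                phase_grid = file.path(out, "phase_grid.tsv"),
                phase_assignments = file.path(out, "phase_assignments.tsv"),
                profiles = file.path(out, "profiles.tsv"),
                features = file.path(out, "features.tsv"),
                manifest = file.path(out, "manifest.json"))
  write_coordinates(diagram, paths$coordinates)
  write_phase_grid(grid, paths$phase_grid)
  write.table(phases, paths$phase_assignments, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_profiles(profiles, paths$profiles)
  write_feature_matrix(feats, paths$features)

  abundance <- NULL; importance <- NULL; overlay <- NULL; stats_tab <- NULL
  if (!is.null(config$annotations_dir)) {
    gffs <- vapply(meta$sample_id, function(sid) {
      for (p in c(".gff3", ".gff")) {
        f <- file.path(config$annotations_dir, paste0(sid, p))
        if (file.exists(f)) return(f)
      }
      NA_character_
    }, character(1))
    ann <- lapply(meta$sample_id[!is.na(gffs)], function(sid)
      parse_gff3_annotations(gffs[[sid]], sample_id = sid))
    .log(config, "info", length(ann), " annotation files parsed")
    if (length(ann)) {
      abundance <- build_abundance_table(ann, meta)
      paths$abundance <- file.path(out, "abundance.tsv")
      write_abundance_table(abundance, paths$abundance)
      if (sum(!is.na(gffs)) >= 4 && length(unique(labels)) >= 2) {
        importance <- c(list(overall = rank_importances(
          abundance, labels, seed = config$seed,
          train_fraction = config$rf_train_fraction,
          num_trees = config$num_trees)),
          per_class_rankings(abundance, labels, seed = config$seed,
                             train_fraction = config$rf_train_fraction,
                             num_trees = config$num_trees))
        paths$importance <- file.path(out, "importance.tsv")
        write_importances(importance, paths$importance)
      }
      if (!is.null(config$overlay_gene)) {
        rng <- if (!is.na(config$colormap_min) && !is.na(config$colormap_max))
          c(config$colormap_min, config$colormap_max) else NULL
        mp <- if (!is.na(config$heat_midpoint)) config$heat_midpoint else NULL
        overlay <- overlay_values(abundance, config$overlay_gene, rng, mp)
        paths$overlay <- file.path(out, "overlay.tsv")
        write.table(overlay, paths$overlay, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        stats_tab <- tryCatch(
          compare_gene_groups(abundance, config$overlay_gene, meta),
          error = function(e) NULL)
        if (!is.null(stats_tab)) {
          paths$stats <- file.path(out, "overlay_stats.tsv")
          write.table(stats_tab$pairwise, paths$stats, sep = "\t",
                      quote = FALSE, row.names = FALSE)
        }
      }
    }
  }

  paths$plot <- file.path(out, paste0("diagram.", config$plot_format))
  render_diagram(diagram, grid, overlay = overlay, file = paths$plot)

  manifest <- list(package = "tetraphase",
                   version = as.character(utils::packageVersion("tetraphase")),
                   r_version = R.version.string,
                   config = unclass(config),
                   n_samples = nrow(meta),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  .log(config, "info", "pipeline artifacts written to ", out)
  invisible(list(metadata = meta, features = feats, diagram = diagram,
                 metrics = metrics, grid = grid, phases = phases,
                 abundance = abundance, importance = importance,
                 overlay = overlay, stats = stats_tab, paths = paths))
}
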