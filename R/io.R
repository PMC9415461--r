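#' Records-table schema
#'
#' Describes the delimited-text dialect of a per-cell records table.
#' The canonical `"wide"` dialect has one row per cell per cycle and one
#' column per parameter; the `"long"` dialect has one row per single
#' measurement (`condition`, `cell_id`, `cycle`, `parameter`, `value`).
#'
#' @param dialect `"wide"` (default) or `"long"`.
#' @param columns Named character vector mapping internal labels
#'   (`condition`, `cell_id`, `cycle`, the eleven parameters, and for the
#'   long dialect `parameter`/`value`) to the external column names in the
#'   file. Defaults to the identity mapping.
#' @param delimiter Field delimiter.
#' @param decimal Decimal mark (`.` or `,`).
#' @return An object of class `records_schema`.
#' @export
records_schema <- function(dialect = c("wide", "long"), columns = NULL,
                           delimiter = ",", decimal = ".") {
  dialect <- match.arg(dialect)
  internal <- c("condition", "cell_id", "cycle",
                if (dialect == "wide") param_names()
                else c("parameter", "value"))
  map <- stats::setNames(internal, internal)
  if (!is.null(columns)) {
    if (is.null(names(columns)) || !all(names(columns) %in% internal))
      stop("schema error: 'columns' names must be internal labels",
           call. = FALSE)
    map[names(columns)] <- columns
  }
  if (anyDuplicated(map))
    stop("schema error: two internal labels map to the same column",
         call. = FALSE)
  structure(list(dialect = dialect, columns = map,
                 delimiter = delimiter, decimal = decimal),
            class = "records_schema")
}

#' Read a per-cell records table
#'
#' @param path File path.
#' @param schema A [records_schema()].
#' @return Records data frame in canonical layout (see
#'   [simulate_trajectories()]; `alive` defaults to `TRUE` when absent).
#' @export
read_records <- function(path, schema = records_schema()) {
  stopifnot(inherits(schema, "records_schema"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = schema$delimiter,
                          dec = schema$decimal, stringsAsFactors = FALSE,
                          check.names = FALSE)
  map <- schema$columns
  missing_cols <- map[!(map %in% names(df))]
  missing_cols <- missing_cols[names(missing_cols) != "alive"]
  if (length(missing_cols))
    stop("missing mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), c(map, "alive", "volume"))
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  sel <- df[, map, drop = FALSE]
  names(sel) <- names(map)
  num_cols <- setdiff(names(sel), c("condition", "cell_id", "parameter"))
  for (cc in num_cols) {
    v <- sel[[cc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stop("non-numeric value in column '", cc, "' at row ",
             which(is.na(vn) & !is.na(v))[1], call. = FALSE)
      sel[[cc]] <- vn
    }
  }
  if (schema$dialect == "long") sel <- long_to_wide(sel)
  sel$cycle <- as.integer(sel$cycle)
  sel$alive <- if ("alive" %in% names(df)) as.logical(df$alive) else TRUE
  if ("volume" %in% names(df)) sel$volume <- df$volume
  ord <- intersect(c(record_id_cols(), param_names(), "volume"), names(sel))
  sel[, ord, drop = FALSE]
}

long_to_wide <- function(sel) {
  bad <- setdiff(unique(sel$parameter), param_names())
  if (length(bad))
    warning("ignoring unknown parameter(s): ", paste(bad, collapse = ", "),
            call. = FALSE)
  sel <- sel[sel$parameter %in% param_names(), , drop = FALSE]
  id <- paste(sel$condition, sel$cell_id, sel$cycle, sep = "\r")
  uid <- unique(id)
  first <- match(uid, id)
  wide <- data.frame(condition = sel$condition[first],
                     cell_id = sel$cell_id[first],
                     cycle = sel$cycle[first],
                     stringsAsFactors = FALSE)
  for (p in intersect(param_names(), unique(sel$parameter))) {
    rows <- sel$parameter == p
    wide[[p]] <- NA_real_
    wide[[p]][match(id[rows], uid)] <- sel$value[rows]
  }
  wide
}

#' Write a per-cell records table
#'
#' @param records Records data frame.
#' @param path File path.
#' @param schema A [records_schema()] (wide dialect only).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, schema = records_schema()) {
  stopifnot(inherits(schema, "records_schema"))
  if (schema$dialect != "wide")
    stop("write_records emits the canonical wide dialect", call. = FALSE)
  cols <- intersect(c("condition", "cell_id", "cycle", "alive",
                      param_names()), names(records))
  out <- records[, cols, drop = FALSE]
  names(out) <- schema$columns[match(cols, names(schema$columns))]
  names(out)[is.na(names(out))] <- cols[is.na(names(out))]
  utils::write.table(out, path, sep = schema$delimiter,
                     dec = schema$decimal, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' The packaged normalized Fourier feature table
#'
#' Loads the worked-example feature table shipped with the package: the
#' dominant-Fourier-amplitude and phase features of four reference
#' conditions (untreated control and three microtubule-targeting
#' treatments, PTX/CLC/VBL) of an NSCLC line, in the pre-normalized form
#' in which the values circulate. Those columns are not unit-variance
#' across the four conditions, so the table is treated as un-normalized
#' input; pass
#' `normalize = TRUE` to apply the pipeline's column z-scoring (the
#' clustering workflow's convention).
#'
#' @param normalize Apply per-column z-scoring across conditions.
#' @return A 4 x 22 `feature_matrix` (rows Control, PTX, CLC, VBL).
#' @examples
#' table2_features()
#' @export
table2_features <- function(normalize = FALSE) {
  df <- table2_fixture()
  params <- param_names()
  conds <- unique(df$sample)
  amp <- as.matrix(df[df$fft_factor == "amplitude", -(1:2)])
  ph <- as.matrix(df[df$fft_factor == "phase", -(1:2)])
  m <- cbind(amp, ph)
  dimnames(m) <- list(conds, c(paste0("amp_", params),
                               paste0("phase_", params)))
  as_feature_matrix(m, normalize)
}

#' @rdname table2_features
#' @return For `table2_fixture()`, the fixture as the data frame read from
#'   disk (columns `fft_factor`, `sample`, and the eleven short parameter
#'   labels).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_normalized_features.csv",
                      package = "phenofft", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a feature table in the fixture's printed layout
#'
#' Formats every numeric cell with exactly two decimals, reproducing the
#' packaged fixture byte-for-byte on a round trip.
#'
#' @param df Data frame shaped like [table2_fixture()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) sprintf("%.2f", v))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run the whole profiling pipeline
#'
#' Simulates replicate conditions for a set of archetypes, aggregates them
#' to condition series, centers/scales, extracts dominant Fourier
#' features, builds the normalized feature matrix, correlates and clusters
#' the conditions, and (when replicate structure allows) scores archetype
#' recovery. Optionally writes every stage artifact plus a JSON manifest
#' that suffices to reproduce the run.
#'
#' @param archetypes List of [archetype_spec()] objects; defaults to
#'   [builtin_archetypes()].
#' @param replicates Simulated replicate conditions per archetype.
#' @param config An [acquisition_config()].
#' @param seed Base seed; replicate `r` of archetype `i` runs with
#'   `seed + 1000 * i + r`.
#' @param linkage Linkage for [cluster_conditions()].
#' @param k Flat cluster count; defaults to the number of archetypes.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return Bundle list: `records`, `series`, `centered`, `features`,
#'   `feature_matrix`, `correlation`, `clusters`, `truth`, `agreement`
#'   (NA when fewer than 2 replicates of 2 archetypes), `manifest`.
#' @examples
#' \donttest{
#' b <- run_pipeline(replicates = 2,
#'                   config = acquisition_config(duration = 2), seed = 1)
#' b$clusters
#' }
#' @export
run_pipeline <- function(archetypes = builtin_archetypes(), replicates = 3,
                         config = acquisition_config(), seed = config$seed,
                         linkage = "average", k = length(archetypes),
                         out_dir = NULL) {
  if (is.null(names(archetypes)))
    names(archetypes) <- vapply(archetypes, `[[`, character(1), "name")
  seeds <- list()
  recs <- list()
  truth <- character()
  for (i in seq_along(archetypes)) {
    for (r in seq_len(replicates)) {
      cond <- sprintf("%s_r%d", names(archetypes)[i], r)
      s <- as.integer(seed + 1000L * i + r)
      seeds[[cond]] <- s
      truth[cond] <- names(archetypes)[i]
      recs[[cond]] <- simulate_trajectories(config, archetypes[[i]],
                                            seed = s, condition = cond)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  series <- aggregate_records(records)
  centered <- lapply(series, center_scale)
  features <- spectral_features(centered)
  fm <- build_feature_matrix(features, normalize = TRUE)
  corr <- condition_correlation(fm)
  clusters <- cluster_conditions(corr, linkage = linkage, k = k)
  agreement <- NA_real_
  if (length(archetypes) >= 2 && replicates >= 2)
    agreement <- archetype_recovery_report(records, truth,
                                           linkage = linkage)$agreement
  manifest <- list(
    package = "phenofft",
    version = as.character(utils::packageVersion("phenofft")),
    seed = seed, replicate_seeds = seeds,
    config = unclass(config), linkage = linkage, k = k,
    conditions = names(recs),
    n_records = nrow(records),
    n_cells = length(unique(paste(records$condition, records$cell_id)))
  )
  bundle <- list(records = records, series = series, centered = centered,
                 features = features, feature_matrix = fm,
                 correlation = corr, clusters = clusters, truth = truth,
                 agreement = agreement, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write_records(bundle$records, fp("records.csv"))
  for (cond in names(bundle$series)) {
    s <- bundle$series[[cond]]
    df <- data.frame(cycle = s$cycles,
                     stats::setNames(as.data.frame(s$mean),
                                     paste0("mean_", colnames(s$mean))),
                     stats::setNames(as.data.frame(s$sd),
                                     paste0("sd_", colnames(s$sd))),
                     n_cells = s$n_cells)
    utils::write.table(df, fp(sprintf("series_%s.csv", cond)), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(
      as.data.frame(parameter_correlation(s)),
      fp(sprintf("paramcorr_%s.csv", cond)), sep = ",",
      row.names = TRUE, col.names = NA, quote = FALSE)
  }
  utils::write.table(bundle$features, fp("fft_features.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  fm <- data.frame(condition = rownames(bundle$feature_matrix),
                   unclass(bundle$feature_matrix), check.names = FALSE)
  utils::write.table(fm, fp("feature_matrix.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(bundle$correlation),
                     fp("condition_corr.csv"), sep = ",",
                     row.names = TRUE, col.names = NA, quote = FALSE)
  cl <- bundle$clusters
  jsonlite::write_json(
    list(linkage = cl$tree$method, k = cl$k,
         clusters = split(names(cl$clusters), cl$clusters),
         merge_heights = cl$tree$height,
         agreement = bundle$agreement),
    fp("clusters.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
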