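## ---- delimited-text readers and writers ----------------------------------

## sniff the field separator from the first line
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a gene-by-time expression matrix from delimited text
#'
#' Expected layout: a header row whose first field names the gene-id column
#' and whose remaining fields are the numeric sampling times (hours), then
#' one row per gene. Tab- and comma-separated dialects are auto-detected.
#'
#' @param path File path.
#' @param condition Condition label; defaults to the file name without
#'   extension.
#' @param sep Field separator; `"auto"` (default) sniffs the header line.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, condition = NULL, sep = "auto") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (identical(sep, "auto")) sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 4L) {
    stop("expression matrix needs a gene-id column and >= 3 time columns: ",
         path, call. = FALSE)
  }
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(times)) {
    stop("non-numeric time(s) in header of ", path, ": ",
         paste(names(df)[-1L][is.na(times)], collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression value(s) in column(s) of ", path, ": ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(condition)) {
    condition <- sub("\\.[^.]*$", "", basename(path))
  }
  expression_matrix(as.matrix(vals), times, condition = condition,
                    gene_ids = gene_ids)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, remaining
#' columns headed by the sampling times, full numeric precision.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_expression_matrix <- function(m, path, sep = "\t") {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE,
                   row.names = NULL)
  names(df)[-1L] <- format(m$times, trim = TRUE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-category annotation table
#'
#' Two delimited columns: gene id and category label (e.g. a GO-slim term);
#' genes with several labels appear on several rows. A header row is kept if
#' its first field is `gene_id`, otherwise the first row is data.
#'
#' @inheritParams read_expression_matrix
#' @return Data frame with columns `gene_id` and `category`.
#' @export
read_annotation <- function(path, sep = "auto") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (identical(sep, "auto")) sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  header <- identical(tolower(first[1L]), "gene_id")
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("annotation needs two columns: ", path,
                          call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("gene_id", "category")
  df$gene_id <- as.character(df$gene_id)
  df$category <- as.character(df$category)
  if (any(!nzchar(df$category))) {
    stop("empty category label(s) in ", path, call. = FALSE)
  }
  df
}

#' Read a permutation entropy table written by the pipeline or CLI
#'
#' @param path TSV with columns `gene_id`, one per condition, and `pe_sum`.
#' @return A `pe_table` object (see [pe_table()]).
#' @export
read_pe_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  conds <- setdiff(names(df), c("gene_id", "pe_sum"))
  pe <- as.matrix(df[, conds, drop = FALSE])
  rownames(pe) <- df$gene_id
  structure(list(gene_ids = df$gene_id, conditions = conds, pe = pe,
                 pe_sum = rowSums(pe), n_windows = NA_integer_,
                 d_e = NA_real_),
            class = "pe_table")
}

## write a data frame as TSV with numeric columns at 6 significant digits
write_tsv_report <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- as.character(signif(df[[j]], 6))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- run configuration and pipeline --------------------------------------

#' Read a pipeline run configuration from YAML
#'
#' Recognized keys: `conditions` (map condition name to matrix file),
#' `control` (name of the control condition), `d_e` (number or `"estimate"`),
#' `replicates` (map condition name to a list of replicate matrix files, used
#' when `d_e: estimate`), `n_drop` (count or fraction; default drops 10,000
#' genes when at least 20,000 are present, none otherwise), `r_threshold`
#' (default 0.98), `q` (degree stratum fraction, default 0.2), `annotation`
#' (optional two-column file), `normalize_to_control` (logical, default
#' FALSE), `output_dir`, `seed`.
#'
#' Relative file paths are resolved against the directory containing the
#' configuration file.
#'
#' @param path YAML file path.
#' @return A `pe_run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  }
  if (is.null(cfg$conditions) || is.null(names(cfg$conditions))) {
    stop("config must map condition names to files under 'conditions'",
         call. = FALSE)
  }
  cfg$conditions <- lapply(cfg$conditions, resolve)
  if (is.null(cfg$control) || !cfg$control %in% names(cfg$conditions)) {
    stop("config 'control' must name one of the conditions", call. = FALSE)
  }
  if (!is.null(cfg$replicates)) {
    cfg$replicates <- lapply(cfg$replicates,
                             function(ps) vapply(ps, resolve, character(1)))
  }
  if (!is.null(cfg$annotation)) cfg$annotation <- resolve(cfg$annotation)
  if (is.null(cfg$d_e)) cfg$d_e <- 0.35
  if (is.null(cfg$r_threshold)) cfg$r_threshold <- 0.98
  if (is.null(cfg$q)) cfg$q <- 0.2
  if (is.null(cfg$normalize_to_control)) cfg$normalize_to_control <- FALSE
  structure(cfg, class = "pe_run_config")
}

#' Run the full entropy analysis pipeline
#'
#' Orchestrates the analysis end to end: read the condition matrices,
#' determine the noise threshold (fixed value or replicate-estimated),
#' filter low-expression genes on the control condition, optionally express
#' stress profiles relative to control, compute the per-gene entropy table,
#' the stress-versus-control shift tests, the category enrichments of the
#' maximal-entropy genes (when an annotation is supplied), the mean entropy
#' per category with its biclustering, and the per-condition
#' correlation-network degree analysis. All outputs are TSV (numbers at 6
#' significant digits) plus a JSON manifest that fully determines a rerun;
#' reruns with the same configuration are byte-identical.
#'
#' @param cfg A `pe_run_config` from [read_run_config()], or the path to the
#'   YAML file.
#' @param out_dir Output directory (default: the config's `output_dir`).
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(out_dir)) out_dir <- cfg$output_dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  log_stage <- function(...) message("[pentropy] ", sprintf(...))

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_stage("%s (%.2f s)", name, proc.time()[["elapsed"]] - t0)
    out
  }

  mats <- stage("read matrices", {
    m <- lapply(names(cfg$conditions), function(cn) {
      read_expression_matrix(cfg$conditions[[cn]], condition = cn)
    })
    names(m) <- names(cfg$conditions)
    m
  })

  d_e_source <- "configured"
  d_e <- if (identical(cfg$d_e, "estimate")) {
    stage("estimate d_e", {
      if (is.null(cfg$replicates)) {
        stop("d_e: estimate requires replicate files", call. = FALSE)
      }
      sets <- lapply(names(cfg$replicates), function(cn) {
        reps <- lapply(cfg$replicates[[cn]], function(p) {
          read_expression_matrix(p, condition = cn)$values
        })
        expression_matrix(reps[[1L]], mats[[cn]]$times, condition = cn,
                          replicates = reps)
      })
      d_e_source <- "replicate-estimated"
      estimate_noise_threshold(sets)$d_e
    })
  } else {
    as.numeric(cfg$d_e)
  }

  filt_stage <- stage("filter low expression", {
    control <- mats[[cfg$control]]
    n_drop <- cfg$n_drop
    if (is.null(n_drop)) {
      n_drop <- if (nrow(control$values) >= 20000L) 10000L else 0L
    }
    f <- filter_low_expression(control, n_drop)
    kept <- f$matrix$gene_ids
    filtered <- lapply(mats, function(m) {
      idx <- match(kept, m$gene_ids)
      if (anyNA(idx)) stop("condition '", m$condition,
                           "' is missing filtered genes", call. = FALSE)
      expression_matrix(m$values[idx, , drop = FALSE], m$times,
                        condition = m$condition, gene_ids = kept)
    })
    list(report = f$report, mats = filtered)
  })
  mats <- filt_stage$mats
  filt <- filt_stage$report

  if (isTRUE(cfg$normalize_to_control)) {
    mats <- stage("normalize to control", {
      ctrl <- mats[[cfg$control]]
      out <- lapply(mats, function(m) {
        if (m$condition == cfg$control) return(m)
        n <- normalize_to_control(m, ctrl)
        n$condition <- m$condition   # keep the original label
        rownames(n$values) <- n$gene_ids
        n
      })
      out
    })
  }

  tab <- stage("entropy table", pe_table(mats, d_e))
  files <- character(0)
  pe_path <- file.path(out_dir, "pe.tsv")
  write_tsv_report(as.data.frame(tab), pe_path)
  files <- c(files, pe_path)

  comparisons <- stage("condition comparisons", {
    stress_conds <- setdiff(tab$conditions, cfg$control)
    if (length(stress_conds) == 0L) NULL else {
      do.call(rbind, lapply(stress_conds, function(sc) {
        cmp <- compare_conditions(tab, sc, cfg$control)
        data.frame(condition = sc, delta_mean = cmp$delta_mean,
                   delta_median = cmp$delta_median, U = cmp$statistic,
                   p = cmp$p.value)
      }))
    }
  })
  if (!is.null(comparisons)) {
    p <- file.path(out_dir, "comparisons.tsv")
    write_tsv_report(comparisons, p)
    files <- c(files, p)
  }

  enrich_out <- NULL
  if (!is.null(cfg$annotation)) {
    ann <- read_annotation(cfg$annotation)
    enrich_out <- stage("enrichment", {
      lapply(tab$conditions, function(cn) {
        k <- match(cn, tab$conditions)
        max_pe <- max(achievable_pe_values(tab$n_windows[k]))
        sel <- tab$gene_ids[tab$pe[, cn] >= max_pe - 1e-9]
        res <- if (length(sel) == 0L) {
          # nothing reaches the maximal entropy: nothing to test
          enrichment(character(0), tab$gene_ids,
                     ann[0, , drop = FALSE])
        } else {
          enrichment(sel, tab$gene_ids, ann)
        }
        p <- file.path(out_dir, paste0("enrichment_", cn, ".tsv"))
        write_tsv_report(res, p)
        files <<- c(files, p)
        res
      })
    })
    cat_pe <- stage("category means", mean_pe_by_category(tab, ann))
    p <- file.path(out_dir, "category_mean_pe.tsv")
    df <- data.frame(category = rownames(cat_pe), cat_pe,
                     check.names = FALSE, row.names = NULL)
    write_tsv_report(df, p)
    files <- c(files, p)
    if (nrow(cat_pe) >= 2L && ncol(cat_pe) >= 2L) {
      bic <- bicluster(cat_pe)
      p <- file.path(out_dir, "category_mean_pe_clustered.tsv")
      df <- data.frame(category = rownames(bic$reordered), bic$reordered,
                       check.names = FALSE, row.names = NULL)
      write_tsv_report(df, p)
      files <- c(files, p)
    }
  }

  degree_out <- stage("correlation degree", {
    lapply(mats, function(m) {
      dt <- correlation_degree(m, cfg$r_threshold)
      p <- file.path(out_dir, paste0("degree_", m$condition, ".tsv"))
      write_tsv_report(data.frame(gene_id = dt$gene_ids,
                                  degree = dt$degree, row.names = NULL), p)
      files <<- c(files, p)
      dt
    })
  })
  strat <- degree_stratified_pe(unname(degree_out), tab, cfg$q)
  p <- file.path(out_dir, "degree_pe.tsv")
  write_tsv_report(strat, p)
  files <- c(files, p)

  manifest <- list(package = "pentropy",
                   version = as.character(utils::packageVersion("pentropy")),
                   seed = cfg$seed, d_e = d_e, d_e_source = d_e_source,
                   n_input = filt$n_input, n_removed = filt$n_removed,
                   n_kept = filt$n_kept,
                   control = cfg$control,
                   conditions = names(cfg$conditions),
                   normalize_to_control = isTRUE(cfg$normalize_to_control),
                   r_threshold = cfg$r_threshold, q = cfg$q,
                   outputs = basename(files))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, mpath)
  invisible(list(pe_table = tab, comparisons = comparisons,
                 enrichment = enrich_out, degree = degree_out,
                 degree_pe = strat, filter_report = filt, d_e = d_e,
                 files = files))
}
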