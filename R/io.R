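#' Read an individual-records CSV
#'
#' Expected header: `district,<covariate columns>,y_mcu,y_shk,weight`.
#' Categories are strings and validated against the schema; `y_shk` may be
#' given either as 0/1 or as the three knowledge levels
#' Poor/Moderate/Good, in which case it is dichotomized on load
#' ([dichotomize_knowledge()]). Rows with missing covariates or outcomes
#' are dropped with a message stating the count (complete-case analysis);
#' structural errors (unknown column values, nonpositive weights) abort
#' with the offending data line number.
#'
#' @param path CSV file path.
#' @param schema covariate schema (default [default_schema()]).
#' @param knowledge_cut passed to [dichotomize_knowledge()].
#' @return Validated records data frame.
#' @export
read_records_csv <- function(path, schema = default_schema(),
                             knowledge_cut = "good") {
  if (!file.exists(path)) stop("records file not found: ", path)
  schema <- validate_schema(schema)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("district", names(schema), "y_mcu", "y_shk", "weight")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("records file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    stop("unknown column(s) in records file: ", paste(extra, collapse = ", "))
  }
  line <- seq_len(nrow(df)) + 1L          # header is line 1
  blank <- function(x) is.na(x) | x == ""
  incomplete <- Reduce(`|`, lapply(df[required], blank))
  if (any(incomplete)) {
    message("dropping ", sum(incomplete),
            " record(s) with missing fields (complete-case analysis)")
    df <- df[!incomplete, , drop = FALSE]
    line <- line[!incomplete]
  }
  if (!nrow(df)) stop("no complete records in ", path)
  check_level <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad)) {
      stop("line ", line[bad[1L]], ": unparseable value '",
           df[[col]][bad[1L]], "' in column '", col, "'")
    }
  }
  for (nm in names(schema)) check_level(nm, schema[[nm]]$categories)
  check_level("y_mcu", c("0", "1"))
  check_level("y_shk", c("0", "1", "Poor", "Moderate", "Good"))
  w <- suppressWarnings(as.numeric(df$weight))
  bad_w <- which(is.na(w) | w <= 0)
  if (length(bad_w)) {
    stop("line ", line[bad_w[1L]], ": nonpositive or unparseable weight '",
         df$weight[bad_w[1L]], "'")
  }
  y_shk <- df$y_shk
  lvl <- y_shk %in% c("Poor", "Moderate", "Good")
  if (any(lvl)) {
    y_shk[lvl] <- as.character(dichotomize_knowledge(y_shk[lvl],
                                                     knowledge_cut))
  }
  out <- df[c("district", names(schema))]
  out$y_mcu <- as.integer(df$y_mcu)
  out$y_shk <- as.integer(y_shk)
  out$weight <- w
  rownames(out) <- NULL
  out
}

#' Write an individual-records CSV
#'
#' Inverse of [read_records_csv()] on valid record frames.
#'
#' @param records records data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- configuration -----------------------------------------------------

spec_to_list <- function(spec) {
  sc <- lapply(spec$covariate_schema, function(cv) {
    list(categories = as.list(cv$categories), reference = cv$reference)
  })
  list(covariate_schema = sc,
       fixed_effect_precision = spec$fixed_effect_precision,
       loading_prior = spec$loading_prior,
       pc_prior = spec$pc_prior[!vapply(spec$pc_prior, is.null, TRUE)],
       loading_mode = spec$loading_mode,
       include_shared = spec$include_shared,
       include_specific = spec$include_specific,
       knowledge_cut = spec$knowledge_cut)
}

list_to_spec <- function(x) {
  sc <- lapply(x$covariate_schema, function(cv) {
    list(categories = unlist(cv$categories), reference = cv$reference)
  })
  pc <- x$pc_prior
  if (is.null(pc$lambda)) pc["lambda"] <- list(NULL)
  model_spec(covariate_schema = sc,
             fixed_effect_precision = x$fixed_effect_precision,
             loading_prior = x$loading_prior,
             pc_prior = pc,
             loading_mode = x$loading_mode,
             include_shared = x$include_shared,
             include_specific = x$include_specific,
             knowledge_cut = x$knowledge_cut)
}

#' Load a model/simulation configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) with optional top-level
#' sections `model` (fields of [model_spec()]) and `simulation` (scalar
#' fields of [sim_config()]: `grid`, `n_per_district`, `alpha`, `delta`,
#' `tau_V`, `tau_S`, `seed`, `preset`). Loading the result of
#' [save_config()] reproduces the same objects (round-trip identity).
#'
#' @param path config file path.
#' @return List with elements `model` (a `sharedcomp_spec` or `NULL`) and
#'   `simulation` (a `sim_config` or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list(model = NULL, simulation = NULL)
  if (!is.null(raw$model)) out$model <- list_to_spec(raw$model)
  if (!is.null(raw$simulation)) {
    s <- raw$simulation
    schema <- if (!is.null(out$model)) out$model$covariate_schema
              else default_schema()
    g <- if (!is.null(s$grid)) grid_graph(s$grid[[1]], s$grid[[2]])
         else grid_graph(6, 5)
    args <- list(graph = g, schema = schema)
    for (f in c("n_per_district", "alpha", "delta", "tau_V", "tau_S",
                "seed")) {
      if (!is.null(s[[f]])) args[[f]] <- unlist(s[[f]])
    }
    if (!is.null(s$preset)) {
      args$alpha <- rep(stats::qlogis(
        switch(s$preset, "uganda-like" = 0.27, "chad-like" = 0.01,
               stop("unknown preset: ", s$preset))), 2)
    }
    if (!is.null(s$covariate_probs)) {
      args$covariate_probs <- lapply(s$covariate_probs, unlist)
    }
    if (!is.null(s$weight_model)) args$weight_model <- s$weight_model
    out$simulation <- do.call(sim_config, args)
  }
  if (is.null(raw$model) && is.null(raw$simulation)) {
    stop("config must contain a 'model' and/or 'simulation' section")
  }
  out
}

#' Save a configuration file
#'
#' @param config list with `model` ([model_spec()]) and/or `simulation`
#'   ([sim_config()]) entries.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- list()
  if (!is.null(config$model)) out$model <- spec_to_list(config$model)
  if (!is.null(config$simulation)) {
    s <- config$simulation
    out$simulation <- list(
      n_per_district = s$n_per_district,
      alpha = s$alpha, delta = s$delta, tau_V = s$tau_V, tau_S = s$tau_S,
      seed = s$seed,
      covariate_probs = lapply(s$covariate_probs, as.list),
      weight_model = s$weight_model)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path, precision = 15L)
  }
  invisible(path)
}

# ---- result writers ----------------------------------------------------

#' Write posterior summaries, surfaces and weighted tables as CSV
#'
#' @param obj object to write: a [summarize_chains()] data frame, a
#'   [district_effect_surface()] data frame, or a [weighted_crosstab()]
#'   result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(obj, path) {
  utils::write.csv(obj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
write_surface <- write_summary

#' @rdname write_summary
#' @export
write_table <- function(obj, path) {
  if (inherits(obj, "weighted_table")) {
    df <- as.data.frame(obj$counts)
    df <- cbind(category = rownames(obj$counts), df,
                pct = obj$percent)
    df$chisq <- obj$statistic
    df$df <- obj$df
    df$p_value <- obj$p_value
    df$p_printed <- if (obj$degenerate) "NA"
                    else if (obj$p_value < 1e-3) "<0.001"
                    else fmt3(obj$p_value)
    obj <- df
  }
  utils::write.csv(obj, path, row.names = FALSE)
  invisible(path)
}

#' Persist and reload MCMC chains as CSV
#'
#' One file per chain (`chain1.csv`, ...), one row per retained draw, one
#' column per scalar parameter, header = parameter names.
#'
#' @param fit a [fit_mcmc()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chains <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in seq_along(fit$chains)) {
    utils::write.csv(as.data.frame(fit$chains[[ch]]),
                     file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_chains
#' @param check.names leave parameter names untouched when reloading.
#' @export
read_chains <- function(dir, check.names = FALSE) {
  files <- sort(list.files(dir, pattern = "^chain[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no chain CSV files in ", dir)
  chains <- lapply(files, function(f) {
    as.matrix(utils::read.csv(f, check.names = check.names))
  })
  structure(list(chains = chains, accept = NULL, graph = NULL,
                 spec = NULL, cfg = NULL, n_records = NA_integer_),
            class = "sharedcomp_fit")
}
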