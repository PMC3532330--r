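# Configuration, persistence and exchange formats: training-set grids,
# YAML network configs, Matrix Market / CSV exports, and
# schema-versioned artifact containers.

#' Tensor grid of training parameters
#'
#' Builds the deterministic training set for basis generation: per
#' parameter, \code{counts} linearly or logarithmically equidistant
#' values spanning its range (endpoints included), combined into a
#' tensor grid enumerated lexicographically with the first parameter
#' varying fastest. A count of 1 degenerates to the lower bound.
#'
#' @param ranges named list of \code{c(lower, upper)} per parameter.
#' @param counts integer count per parameter (recycled).
#' @param spacing \code{"log"} (default; requires positive bounds) or
#'   \code{"linear"}.
#' @return numeric matrix, one parameter vector per row, named columns.
#' @examples
#' make_training_set(list(u1 = c(0.005, 0.02), u2 = c(0.005, 0.02)), 9)
#' @export
make_training_set <- function(ranges, counts, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  counts <- rep(as.integer(counts), length.out = length(ranges))
  if (any(counts < 1L)) stop("counts must be >= 1")
  axes <- lapply(seq_along(ranges), function(i) {
    rng <- ranges[[i]]
    if (counts[i] == 1L) return(rng[1])
    ax <- if (spacing == "log") {
      if (any(rng <= 0)) stop("log spacing requires positive bounds")
      exp(seq(log(rng[1]), log(rng[2]), length.out = counts[i]))
    } else seq(rng[1], rng[2], length.out = counts[i])
    ax[1] <- rng[1]                      # pin endpoints exactly
    ax[counts[i]] <- rng[2]
    ax
  })
  names(axes) <- names(ranges)
  as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

# --- YAML network configs ---------------------------------------------

parse_state_expr <- function(expr_text, species) {
  expr <- parse(text = expr_text)[[1]]
  force(species)
  function(states) {
    env <- new.env(parent = baseenv())
    for (i in seq_along(species)) assign(species[i], states[, i], envir = env)
    val <- eval(expr, env)
    rep_len(as.numeric(val), nrow(states))
  }
}

parse_coef_expr <- function(expr_text) {
  expr <- parse(text = expr_text)[[1]]
  function(theta) as.numeric(eval(expr, theta, baseenv()))
}

parse_predicate_expr <- function(expr_text, species) {
  expr <- parse(text = expr_text)[[1]]
  function(states) {
    env <- new.env(parent = baseenv())
    for (i in seq_along(species)) assign(species[i], states[, i], envir = env)
    as.logical(eval(expr, env))
  }
}

#' Read a reaction-network model from a YAML config
#'
#' Builds a complete \code{cme_model} from a declarative YAML file with
#' fields \code{species}, \code{bounds} (\code{lower}/\code{upper}),
#' \code{parameters} (nominal values), \code{domain} (admissible ranges
#' of the varied parameters), \code{reactions} (reactant/product
#' stoichiometries), \code{propensities} (per separable term: reaction
#' index, \code{coef} expression over parameter names, \code{state}
#' expression over species names, optional label), \code{init} (a
#' predicate expression selecting the uniformly weighted initial
#' support), \code{T}, and \code{outputs} (list of
#' \code{kind: expectation|region} specs). Expressions are parsed as
#' plain arithmetic R expressions over the declared names.
#'
#' @param path YAML file path.
#' @return a \code{cme_model}.
#' @export
read_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("species", "bounds", "reactions", "propensities", "init"))
    if (is.null(cfg[[field]])) stop("model config is missing field '", field, "'")
  species <- as.character(cfg$species)
  reactions <- lapply(cfg$reactions, function(r)
    list(reactant = as.integer(r$reactant), product = as.integer(r$product),
         name = r$name))
  props <- lapply(cfg$propensities, function(p) {
    g <- if (!is.null(p$mass_action) && isTRUE(p$mass_action))
      mass_action_g(reactions[[p$reaction]]$reactant)
    else parse_state_expr(p$state, species)
    propensity_term(p$reaction, parse_coef_expr(p$coef), g,
                    label = if (is.null(p$label)) p$coef else p$label)
  })
  net <- reaction_network(species, reactions, props)
  ss <- state_space(cfg$bounds$lower, cfg$bounds$upper, species = species)
  domain <- lapply(cfg$domain, as.numeric)
  po <- parametric_operator(net, ss,
                            domain = if (length(domain)) domain else NULL)
  P0 <- initial_uniform(ss, parse_predicate_expr(cfg$init, species),
                        description = cfg$init)
  outputs <- list()
  for (o in cfg$outputs) {
    om <- switch(o$kind,
      expectation = output_expectation(ss, o$species),
      region = output_region(ss, parse_predicate_expr(o$predicate, species),
                             label = if (is.null(o$label)) o$predicate else o$label),
      stop("unknown output kind '", o$kind, "'"))
    outputs[[length(outputs) + 1L]] <- om
  }
  names(outputs) <- vapply(outputs, function(o) o$labels[1], "")
  new_cme_model(if (is.null(cfg$name)) basename(path) else cfg$name,
                net, ss, po, P0, outputs,
                params = lapply(cfg$parameters, as.numeric),
                varied = domain,
                T_final = if (is.null(cfg$T)) 1 else as.numeric(cfg$T),
                units = if (is.null(cfg$units)) "a.u." else cfg$units)
}

# --- exchange formats -------------------------------------------------

#' Export the sparse operator components to Matrix Market files
#' @param po a [parametric_operator()].
#' @param dir output directory (created if needed); one
#'   \code{component_<q>_<label>.mtx} file per component.
#' @return invisibly, the written file paths.
#' @export
export_components_mtx <- function(po, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(po$Q)
  for (q in seq_len(po$Q)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", po$labels[q])
    paths[q] <- file.path(dir, sprintf("component_%02d_%s.mtx", q, safe))
    Matrix::writeMM(po$components[[q]], paths[q])
  }
  invisible(paths)
}

#' Export the enumerated state table to CSV
#' @param ss a [state_space()].
#' @param path CSV output path; columns \code{index, x1..xn}.
#' @export
export_states_csv <- function(ss, path) {
  utils::write.csv(as.data.frame(ss), path, row.names = FALSE)
  invisible(path)
}

# --- artifact containers ----------------------------------------------

ARTIFACT_SCHEMA <- "cmerb/1"

#' Save a package artifact (basis, reduced model, trajectory, report)
#'
#' Serializes the object into a schema-versioned container so that
#' loading can detect incompatible or corrupt files. Reduced models are
#' self-contained: they reload and solve without the full operator.
#'
#' @param x object to store.
#' @param path destination file.
#' @export
save_artifact <- function(x, path) {
  saveRDS(list(schema = ARTIFACT_SCHEMA, class = class(x)[1],
               created = format(Sys.time(), tz = "UTC"), object = x),
          path, version = 2)
  invisible(path)
}

#' Load a package artifact
#' @param path file written by [save_artifact()].
#' @param expect_class optional class name to require.
#' @return the stored object.
#' @export
load_artifact <- function(path, expect_class = NULL) {
  container <- tryCatch(readRDS(path), error = function(e)
    stop(structure(class = c("cmerb_io_error", "error", "condition"),
                   list(message = paste0("cannot read artifact '", path,
                                         "': ", conditionMessage(e)),
                        call = NULL))))
  if (!is.list(container) || !identical(container$schema, ARTIFACT_SCHEMA))
    stop(structure(class = c("cmerb_io_error", "error", "condition"),
                   list(message = paste0("'", path,
                                         "' is not a cmerb artifact (schema mismatch)"),
                        call = NULL)))
  if (!is.null(expect_class) && !identical(container$class, expect_class))
    stop(structure(class = c("cmerb_io_error", "error", "condition"),
                   list(message = sprintf("artifact holds a '%s', expected '%s'",
                                          container$class, expect_class),
                        call = NULL)))
  container$object
}

#' Write a reproducibility manifest for a run
#' @param path JSON destination.
#' @param config the run configuration (any serializable list).
#' @param seeds named list of seeds used.
#' @export
write_manifest <- function(path, config, seeds = list()) {
  manifest <- list(
    package = "cmerb",
    version = as.character(utils::packageVersion("cmerb")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC"),
    config_hash = model_hash(config),
    seeds = seeds,
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
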