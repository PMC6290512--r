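#' Tidy a fitted naive-Bayes meta-classifier
#'
#' @param x An `nb_meta` object.
#' @param ... Unused.
#' @return A tibble with one row per (base classifier, class, label):
#'   the smoothed conditional probability `P(label | class)`, plus the
#'   class prior.
#' @method tidy nb_meta
#' @export
tidy.nb_meta <- function(x, ...) {
  purrr::imap_dfr(x$conditionals, function(tab, base) {
    as_tibble(as.data.frame(as.table(tab))) |>
      setNames(c("class", "label", "probability")) |>
      dplyr::mutate(base = base, .before = 1)
  }) |>
    dplyr::mutate(class = as.character(.data$class),
                  label = as.character(.data$label)) |>
    dplyr::left_join(
      tibble(class = names(x$priors), prior = unname(x$priors)),
      by = "class"
    )
}

#' @describeIn tidy.nb_meta One-row summary: classes, alphabet size,
#'   number of base classifiers, smoothing constant.
#' @method glance nb_meta
#' @export
glance.nb_meta <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_base = length(x$conditionals),
    alphabet_size = length(x$alphabet),
    alpha = x$alpha
  )
}

#' Tidy a fitted hierarchical meta-classifier
#'
#' @param x A `hier_mc` object.
#' @param ... Unused.
#' @return The meta-classifier's conditional-probability table (see
#'   [tidy.nb_meta()]).
#' @method tidy hier_mc
#' @export
tidy.hier_mc <- function(x, ...) {
  tidy(x$coarse$nb)
}

#' @describeIn tidy.hier_mc One-row fit summary: ensemble size, balanced
#'   subset size, unused majority records, classifier family and seeds.
#' @method glance hier_mc
#' @export
glance.hier_mc <- function(x, ...) {
  sm <- x$coarse$subsets_meta
  tibble(
    M = sm$M,
    subset_size = 2L * sm$minority_size,
    n_unused_majority = sm$n_unused_majority,
    base_method = x$spec$method,
    refinement_method = x$refine$spec$method,
    partition_seed = x$seeds[["partition"]],
    base_seed = x$seeds[["base"]]
  )
}

#' Save or load a fitted model bundle
#'
#' The bundle is a single serialized file holding the fitted model (coarse
#' ensemble, meta-classifier tables and refinement model for `hier_mc`),
#' the schema fingerprint and all seeds, plus a format version.
#'
#' @param model A fitted `stage_model`.
#' @param path Bundle file path.
#' @return `save_model()` invisibly returns `path`; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "hiermc-bundle", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("Model bundle not found: ", path))
  bundle <- readRDS(path)
  if (!identical(bundle$format, "hiermc-bundle")) {
    abort("Not a model bundle written by save_model().")
  }
  bundle$model
}
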