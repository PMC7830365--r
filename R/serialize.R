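#' @title Model serialization
#' @description JSON persistence for SCR, RBF-SCR and consensus models.
#'   Numbers are written at full precision (`digits = NA`) so that a
#'   serialize/deserialize/serialize round trip is byte-identical and
#'   reloaded models predict exactly as the originals.
#' @name serialize
NULL

mat_to_list <- function(m) {
  list(values = as.numeric(m), dim = dim(m),
       rownames = rownames(m), colnames = colnames(m))
}

mat_from_list <- function(l) {
  m <- matrix(l$values, l$dim[1], l$dim[2])
  if (!is.null(l$rownames) && length(l$rownames) > 0) rownames(m) <- l$rownames
  if (!is.null(l$colnames) && length(l$colnames) > 0) colnames(m) <- l$colnames
  m
}

named_to_list <- function(x) list(names = names(x), values = unname(x))
named_from_list <- function(l) stats::setNames(as.numeric(l$values), l$names)

scr_to_list <- function(m) {
  list(class = "ao_scr", selected = m$selected, a = named_to_list(m$a),
       v = named_to_list(m$v), n_train = m$n_train, n_vars = m$n_vars,
       sigma2 = m$sigma2, intercept = m$intercept,
       feature_names = m$feature_names)
}

scr_from_list <- function(l) {
  structure(list(selected = as.character(l$selected),
                 a = named_from_list(l$a), v = named_from_list(l$v),
                 n_train = l$n_train, n_vars = l$n_vars, sigma2 = l$sigma2,
                 intercept = l$intercept,
                 feature_names = as.character(l$feature_names)),
            class = "ao_scr")
}

rbf_to_list <- function(m) {
  list(class = "ao_rbf_scr", centers = mat_to_list(m$centers), w = m$w,
       y = m$y, feat_weights = named_to_list(m$feat_weights),
       feature_names = m$feature_names)
}

rbf_from_list <- function(l) {
  structure(list(centers = mat_from_list(l$centers), w = as.numeric(l$w),
                 y = as.numeric(l$y),
                 feat_weights = named_from_list(l$feat_weights),
                 feature_names = as.character(l$feature_names)),
            class = "ao_rbf_scr")
}

featurizer_to_list <- function(fz) {
  list(config = unclass(fz$config), s_p = fz$s_p, s_q = fz$s_q,
       vocab = fz$vocab,
       norm = list(mean = named_to_list(fz$norm$mean),
                   sd = named_to_list(fz$norm$sd),
                   features = fz$norm$features, zero_var = fz$norm$zero_var),
       feature_names = fz$feature_names, kinds = fz$kinds)
}

featurizer_from_list <- function(l) {
  structure(list(
    config = do.call(ao_config, l$config),
    s_p = l$s_p, s_q = l$s_q, vocab = as.character(l$vocab),
    norm = structure(list(mean = named_from_list(l$norm$mean),
                          sd = named_from_list(l$norm$sd),
                          features = as.character(l$norm$features),
                          zero_var = as.character(unlist(l$norm$zero_var))),
                     class = "ao_norm"),
    feature_names = as.character(l$feature_names),
    kinds = as.character(l$kinds)
  ), class = "ao_featurizer")
}

consensus_to_list <- function(m) {
  list(
    class = "ao_consensus",
    descriptor_type = m$descriptor_type,
    n_partials = m$n_partials,
    seed = m$seed,
    config = unclass(m$config),
    ids = m$ids,
    y = m$y,
    train_pred = m$train_pred,
    training_range = named_to_list(m$training_range),
    featurizer = featurizer_to_list(m$featurizer),
    ad = list(X = mat_to_list(m$ad$X), knn_mean = m$ad$knn_mean,
              sim_threshold = m$ad$sim_threshold, centroid = m$ad$centroid,
              G = mat_to_list(m$ad$G), p_eff = m$ad$p_eff, n = m$ad$n,
              leverage_threshold = m$ad$leverage_threshold,
              cv_resid = m$ad$cv_resid, rmse_train = m$ad$rmse_train,
              accuracy_threshold = m$ad$accuracy_threshold, knn = m$ad$knn),
    partials = lapply(m$partials, function(p) {
      list(descriptor_type = p$descriptor_type, features = p$features,
           seed = p$seed, train_r2 = p$train_r2,
           scr = scr_to_list(p$scr), rbf = rbf_to_list(p$rbf))
    })
  )
}

consensus_from_list <- function(l) {
  ad <- l$ad
  structure(list(
    descriptor_type = l$descriptor_type,
    n_partials = l$n_partials,
    partials = lapply(l$partials, function(p) {
      list(descriptor_type = p$descriptor_type,
           features = as.character(p$features), seed = p$seed,
           scr = scr_from_list(p$scr), rbf = rbf_from_list(p$rbf),
           train_r2 = p$train_r2, oob = NULL)
    }),
    featurizer = featurizer_from_list(l$featurizer),
    seed = l$seed,
    config = do.call(ao_config, l$config),
    ids = as.character(l$ids),
    y = as.numeric(l$y),
    train_pred = as.numeric(l$train_pred),
    training_range = named_from_list(l$training_range),
    ad = list(X = mat_from_list(ad$X), knn_mean = as.numeric(ad$knn_mean),
              sim_threshold = ad$sim_threshold,
              centroid = as.numeric(ad$centroid), G = mat_from_list(ad$G),
              p_eff = ad$p_eff, n = ad$n,
              leverage_threshold = ad$leverage_threshold,
              cv_resid = as.numeric(ad$cv_resid),
              rmse_train = ad$rmse_train,
              accuracy_threshold = ad$accuracy_threshold, knn = ad$knn)
  ), class = "ao_consensus")
}

model_to_list <- function(model) {
  switch(class(model)[1],
         ao_scr = scr_to_list(model),
         ao_rbf_scr = rbf_to_list(model),
         ao_consensus = consensus_to_list(model),
         stop("cannot serialize objects of class ", class(model)[1]))
}

#' Serialize a model to JSON
#'
#' Handles `ao_scr`, `ao_rbf_scr` and `ao_consensus` objects. The
#' consensus JSON acts as the ensemble manifest: its `partials` array
#' holds one entry per partial regression.
#'
#' @param model A fitted model object.
#' @param path Output path; when NULL the JSON string is returned.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_model_json <- function(model, path = NULL) {
  # normalize negative zeros: "-0" would not survive a JSON round trip
  lst <- rapply(model_to_list(model), function(x) {
    if (is.numeric(x)) x[x == 0] <- 0
    x
  }, how = "replace")
  # 17 significant digits round-trip IEEE doubles losslessly
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = I(17),
                         null = "null", pretty = FALSE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Load a model from JSON
#'
#' @param path Path to a JSON file written by [write_model_json()] (or
#'   a JSON string).
#' @return The reconstructed model object.
#' @export
read_model_json <- function(path) {
  l <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  switch(as.character(l$class),
         ao_scr = scr_from_list(l),
         ao_rbf_scr = rbf_from_list(l),
         ao_consensus = consensus_from_list(l),
         stop("unrecognised model class in JSON: ", l$class))
}
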