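# JSON persistence for fitted models: explicit state order, plain
# matrices, reproducible round trip.

mat_to_list <- function(m) list(data = as.numeric(m), nrow = nrow(m),
                                ncol = ncol(m), rn = rownames(m),
                                cn = colnames(m))

list_to_mat <- function(l) {
  m <- matrix(l$data, l$nrow, l$ncol)
  if (!is.null(l$rn) && length(l$rn)) rownames(m) <- unlist(l$rn)
  if (!is.null(l$cn) && length(l$cn)) colnames(m) <- unlist(l$cn)
  m
}

#' Write / read HMM parameters as JSON
#'
#' @param params An [hmm_params()] object.
#' @param path JSON file path.
#' @return `path` invisibly (write); the parameters (read).
#' @export
write_hmm_json <- function(params, path) {
  jsonlite::write_json(list(states = params$states,
                            pi = as.numeric(params$pi),
                            trans = mat_to_list(params$trans),
                            emis = if (!is.null(params$emis))
                              mat_to_list(params$emis)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_params(j$pi, list_to_mat(j$trans),
             if (!is.null(j$emis)) list_to_mat(j$emis),
             states = j$states)
}

#' Write / read a fitted psychstate model as JSON
#'
#' Serializes the pipeline (imputation medians, min-max bounds,
#' selected features, PCA basis, discriminant coefficients and
#' landmarks), the emission codebook and the HMM so a stored model
#' reproduces its transform bit-for-bit.
#'
#' @param fit A fitted [psychstate()] model.
#' @param path JSON file path.
#' @return `path` invisibly (write); the model (read).
#' @export
write_model_json <- function(fit, path) {
  p <- fit$pipeline
  obj <- list(
    medians = as.list(p$medians),
    bounds = mat_to_list(p$bounds),
    selected = p$selected,
    pca = list(basis = mat_to_list(p$pca$basis),
               explained = p$pca$explained,
               center = as.list(p$pca$center)),
    gda = list(alpha = mat_to_list(p$gda$alpha),
               landmarks = mat_to_list(p$gda$landmarks),
               kernel = p$gda$kernel, sigma = p$gda$sigma,
               eps = p$gda$eps, classes = p$gda$classes),
    codebook = mat_to_list(fit$codebook),
    hmm = list(states = fit$hmm$states, pi = as.numeric(fit$hmm$pi),
               trans = mat_to_list(fit$hmm$trans),
               emis = mat_to_list(fit$hmm$emis)),
    algo = fit$algo, feature_names = fit$feature_names, seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gda <- structure(list(alpha = list_to_mat(j$gda$alpha),
                        landmarks = list_to_mat(j$gda$landmarks),
                        kernel = j$gda$kernel, sigma = j$gda$sigma,
                        eps = j$gda$eps, classes = j$gda$classes),
                   class = "psych_gda")
  pipeline <- structure(list(
    medians = unlist(j$medians), bounds = list_to_mat(j$bounds),
    selected = j$selected,
    pca = list(basis = list_to_mat(j$pca$basis), explained = j$pca$explained,
               center = unlist(j$pca$center)),
    gda = gda), class = "psych_pipeline")
  hmm <- hmm_params(j$hmm$pi, list_to_mat(j$hmm$trans),
                    list_to_mat(j$hmm$emis), states = j$hmm$states)
  structure(list(pipeline = pipeline, codebook = list_to_mat(j$codebook),
                 hmm = hmm, states = hmm$states, algo = j$algo,
                 feature_names = j$feature_names, seed = j$seed),
            class = "psychstate")
}
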