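# substrate: a categorical naive Bayes classifier mapping pocket residue
# vectors to aminoacyl-tRNA substrates, with strict and physicochemically
# relaxed evaluation, leave-one-out cross-validation, and fold-enrichment
# reporting.

#' Pocket-residue training set
#'
#' @param site `"P1"` or `"P2"` (metadata)
#' @param vectors character matrix, one row per example, one column per
#'   pocket position; `-` is a legal category (gapped pocket position)
#' @param labels amino-acid substrate label per row
#' @return object of class `training_set`
#' @export
training_set <- function(site, vectors, labels) {
  vectors <- as.matrix(vectors)
  stopifnot(nrow(vectors) == length(labels))
  bad <- setdiff(unique(as.vector(vectors)), AA_GAP)
  if (length(bad)) stopf("illegal residue category: %s", bad[1L])
  if (!all(labels %in% AA20)) stopf("labels must be standard amino acids")
  structure(list(site = site, vectors = unname(vectors),
                 labels = as.character(labels)),
            class = "training_set")
}

#' Read a training table (TSV: site, residues, label)
#' @param path TSV with columns `site`, `residues`, `label`
#' @param site which site to keep
#' @return [training_set()]
#' @export
read_training_tsv <- function(path, site = c("P1", "P2")) {
  site <- match.arg(site)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[df$site == site, , drop = FALSE]
  if (!nrow(df)) stopf("no %s rows in %s", site, path)
  training_set(site, do.call(rbind, strsplit(df$residues, "")), df$label)
}

#' Train the substrate naive Bayes model
#'
#' Priors are class frequencies; per-position likelihoods are
#' Laplace-smoothed categorical frequencies over the 21 residue categories
#' (20 amino acids + gap).  Smoothing is required: an unseen pocket residue
#' must never zero a posterior.
#'
#' @param training a [training_set()]
#' @param alpha Laplace smoothing weight (> 0)
#' @return object of class `nb_model`
#' @export
nb_train <- function(training, alpha = 1.0) {
  stopifnot(alpha > 0, length(training$labels) >= 1L)
  classes <- sort(unique(training$labels))
  npos <- ncol(training$vectors)
  priors <- as.numeric(table(factor(training$labels, classes)))
  priors <- priors / sum(priors)
  names(priors) <- classes
  lik <- array(0, dim = c(npos, length(classes), length(AA_GAP)),
               dimnames = list(NULL, classes, AA_GAP))
  for (cl in classes) {
    rows <- training$vectors[training$labels == cl, , drop = FALSE]
    for (p in seq_len(npos)) {
      cnt <- table(factor(rows[, p], AA_GAP))
      lik[p, cl, ] <- (as.numeric(cnt) + alpha) /
        (nrow(rows) + alpha * length(AA_GAP))
    }
  }
  structure(list(site = training$site, classes = classes, priors = priors,
                 likelihoods = lik, smoothing_alpha = alpha,
                 n_positions = npos),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> site %s: %d classes, %d positions, alpha %.2g\n",
              x$site, length(x$classes), x$n_positions, x$smoothing_alpha))
  invisible(x)
}

#' Predict the substrate for one pocket residue vector
#'
#' Posterior is prior times the product of per-position likelihoods,
#' normalized; computed in log space.  Ties in the argmax are broken
#' alphabetically (classes are stored sorted).
#'
#' @param model an [nb_model()]
#' @param vector residue vector (character vector or string), `-` allowed
#' @return list with `site`, `label`, `posterior`, and `ranking`
#'   (data.frame label/posterior, descending)
#' @export
nb_predict <- function(model, vector) {
  if (length(vector) == 1L && nchar(vector[1L]) > 1L) vector <- chars(vector)
  stopifnot(length(vector) == model$n_positions)
  cat_idx <- match(vector, AA_GAP)
  if (anyNA(cat_idx)) stopf("illegal residue category '%s'",
                            vector[is.na(cat_idx)][1L])
  logp <- log(model$priors)
  for (p in seq_len(model$n_positions))
    logp <- logp + log(model$likelihoods[p, , cat_idx[p]])
  logp <- logp - max(logp)
  post <- exp(logp) / sum(exp(logp))
  ord <- order(-post, model$classes)
  list(site = model$site,
       label = model$classes[ord[1L]],
       posterior = unname(post[ord[1L]]),
       ranking = data.frame(label = model$classes[ord],
                            posterior = unname(post[ord]),
                            stringsAsFactors = FALSE))
}

#' Default physicochemical partition of the 20 amino acids
#'
#' A stand-in partition by side-chain character (aliphatic, aromatic,
#' polar, acidic, basic, plus the three singletons C, G, P); the published
#' cluster table it emulates is not printed in our sources, so the
#' partition ships as an editable data file
#' (`system.file("extdata/physchem_clusters.json", package =
#' "cdpsminer")`).
#'
#' @return named list of residue groups
#' @export
default_physchem_clusters <- function() {
  list(aliphatic = c("A", "V", "L", "I", "M"),
       aromatic = c("F", "W", "Y"),
       polar = c("S", "T", "N", "Q"),
       acidic = c("D", "E"),
       basic = c("K", "R", "H"),
       cysteine = "C", glycine = "G", proline = "P")
}

#' Load a physicochemical partition from JSON
#' @param path JSON file: named lists of residues
#' @return named list, validated to partition the 20 amino acids
#' @export
read_physchem_clusters <- function(path) {
  cl <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_physchem(cl)
  cl
}

validate_physchem <- function(clusters) {
  all_res <- unlist(clusters)
  if (anyDuplicated(all_res) || !setequal(all_res, AA20))
    stopf("physicochemical clusters must partition the 20 amino acids")
  invisible(clusters)
}

#' Relaxed (physicochemical) label match
#'
#' @param predicted,truth amino-acid labels
#' @param clusters partition from [default_physchem_clusters()] or
#'   [read_physchem_clusters()]
#' @return `TRUE` iff the labels are equal or share a cluster
#' @export
relaxed_match <- function(predicted, truth,
                          clusters = default_physchem_clusters()) {
  stopifnot(predicted %in% AA20, truth %in% AA20)
  if (predicted == truth) return(TRUE)
  grp <- function(a) which(vapply(clusters, function(g) a %in% g, TRUE))
  grp(predicted) == grp(truth)
}

#' Leave-one-out cross-validation of substrate prediction
#'
#' @param training a [training_set()]
#' @param clusters physicochemical partition for the relaxed metric
#' @param alpha Laplace smoothing weight
#' @return list with `strict_accuracy`, `relaxed_accuracy`, `confusion`
#'   (table truth x predicted), and `predictions`
#' @export
nb_loocv <- function(training, clusters = default_physchem_clusters(),
                     alpha = 1.0) {
  n <- length(training$labels)
  stopifnot(n >= 2L)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- training_set(training$site,
                       training$vectors[-i, , drop = FALSE],
                       training$labels[-i])
    pred[i] <- nb_predict(nb_train(tr, alpha), training$vectors[i, ])$label
  }
  strict <- mean(pred == training$labels)
  relaxed <- mean(mapply(relaxed_match, pred, training$labels,
                         MoreArgs = list(clusters = clusters)))
  list(strict_accuracy = strict,
       relaxed_accuracy = relaxed,
       confusion = table(truth = training$labels, predicted = pred),
       predictions = pred)
}

#' Overall substrate accuracy (mean of the two sites)
#'
#' @param p1,p2 per-site accuracies in percent (0..100)
#' @return their arithmetic mean, rounded to one decimal for reporting
#' @export
overall_accuracy <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 100, p2 >= 0, p2 <= 100)
  round((p1 + p2) / 2, 1L)
}

#' Fold enrichment of an accuracy over a random baseline
#'
#' Two baseline policies are reported because "random expectation" admits
#' both readings: `uniform` = 1/K over the K observed classes;
#' `prior_matched` = sum of squared class priors (the accuracy of a
#' random predictor that draws labels from the class distribution).
#'
#' @param accuracy fraction in (0, 1]
#' @param labels training labels (to derive the baselines), or
#' @param baseline an explicit baseline fraction (> 0), overriding `labels`
#' @param policy `"uniform"` or `"prior_matched"`
#' @return fold enrichment (accuracy / baseline)
#' @export
enrichment <- function(accuracy, labels = NULL, baseline = NULL,
                       policy = c("uniform", "prior_matched")) {
  policy <- match.arg(policy)
  if (is.null(baseline)) {
    stopifnot(!is.null(labels))
    p <- as.numeric(table(labels)) / length(labels)
    baseline <- if (policy == "uniform") 1 / length(p) else sum(p^2)
  }
  if (baseline <= 0) stopf("enrichment baseline must be positive")
  accuracy / baseline
}
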