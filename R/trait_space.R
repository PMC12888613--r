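#' @useDynLib traitlearn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dnorm optim optimize quantile rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

big_five <- c("Neuroticism", "Extraversion", "Openness",
              "Agreeableness", "Conscientiousness")

#' Build a trait lexicon
#'
#' Constructs the trait space of the learning task: an ordered table of trait
#' adjectives, each assigned to one Big Five factor and a social valence
#' (positive or negative), together with the rating-scale bounds. The default
#' configuration reproduces the task design: 40 traits, between 7 and 9 per
#' factor, exactly 20 positive and 20 negative, rated on a 1-8 scale.
#'
#' Trait labels are configurable placeholders (`"N1_pos"`, ...); the factor and
#' valence structure, not the word list, is what the models consume.
#'
#' @param factor_counts Named integer vector, traits per Big Five factor.
#'   The default `c(8, 8, 8, 8, 8)` gives the canonical 40-trait space.
#' @param positive_per_factor Named integer vector, how many traits of each
#'   factor are positively valenced. Defaults to half of each factor's count.
#' @param labels Optional character vector of trait labels (length = total
#'   trait count); autogenerated when `NULL`.
#' @param scale_min,scale_max Integer rating-scale bounds (defaults 1 and 8).
#' @param strict When `TRUE` (default), enforce the published design
#'   constraints: 40 traits total, 7-9 per factor, 20 positive / 20 negative.
#'   Set `FALSE` to build reduced lexicons (e.g. for quick simulations).
#' @return A `trait_lexicon`: a data.frame with columns `trait_id` (1-based),
#'   `label`, `factor`, `valence`, and attributes `scale_min`, `scale_max`.
#' @export
#' @examples
#' lex <- build_default_lexicon()
#' nrow(lex)              # 40
#' table(lex$valence)     # 20 / 20
build_default_lexicon <- function(factor_counts = setNames(rep(8L, 5), big_five),
                                  positive_per_factor = NULL,
                                  labels = NULL,
                                  scale_min = 1L, scale_max = 8L,
                                  strict = TRUE) {
  if (is.null(names(factor_counts))) names(factor_counts) <- big_five[seq_along(factor_counts)]
  if (!all(names(factor_counts) %in% big_five))
    stop("factor_counts names must be Big Five factors: ", paste(big_five, collapse = ", "))
  factor_counts <- setNames(as.integer(factor_counts), names(factor_counts))
  if (is.null(positive_per_factor)) {
    # alternate the rounding so totals split evenly
    positive_per_factor <- floor(factor_counts / 2) +
      (seq_along(factor_counts) %% 2L) * (factor_counts %% 2L)
    names(positive_per_factor) <- names(factor_counts)
  }
  n_total <- sum(factor_counts)
  n_pos <- sum(positive_per_factor)
  if (strict) {
    if (n_total != 40L)
      stop("strict lexicon requires 40 traits in total, got ", n_total)
    if (any(factor_counts < 7L | factor_counts > 9L))
      stop("strict lexicon requires between 7 and 9 traits per factor")
    if (n_pos != 20L)
      stop("strict lexicon requires 20 positive and 20 negative traits, got ",
           n_pos, " positive")
  }
  if (any(positive_per_factor < 0L) || any(positive_per_factor > factor_counts))
    stop("positive_per_factor out of range for factor_counts")
  if (scale_min >= scale_max) stop("scale_min must be below scale_max")

  fac <- rep(names(factor_counts), factor_counts)
  val <- unlist(lapply(seq_along(factor_counts), function(i) {
    c(rep("positive", positive_per_factor[i]),
      rep("negative", factor_counts[i] - positive_per_factor[i]))
  }), use.names = FALSE)
  if (is.null(labels)) {
    abbr <- substr(fac, 1L, 1L)
    within <- unlist(lapply(factor_counts, seq_len), use.names = FALSE)
    labels <- paste0(abbr, within, "_", ifelse(val == "positive", "pos", "neg"))
  }
  if (length(labels) != n_total) stop("labels length must equal total trait count")
  if (anyDuplicated(labels)) stop("trait labels must be unique")

  lex <- data.frame(trait_id = seq_len(n_total), label = labels,
                    factor = fac, valence = val, stringsAsFactors = FALSE)
  attr(lex, "scale_min") <- as.integer(scale_min)
  attr(lex, "scale_max") <- as.integer(scale_max)
  class(lex) <- c("trait_lexicon", "data.frame")
  lex
}

#' @export
print.trait_lexicon <- function(x, ...) {
  cat("Trait lexicon:", nrow(x), "traits, scale",
      attr(x, "scale_min"), "-", attr(x, "scale_max"), "\n")
  print(table(factor = x$factor, valence = x$valence))
  invisible(x)
}

scale_bounds <- function(lexicon) {
  c(attr(lexicon, "scale_min"), attr(lexicon, "scale_max"))
}

scale_midpoint <- function(lexicon) {
  mean(scale_bounds(lexicon))
}

#' Reverse-code a rating on a negative trait
#'
#' Maps ratings so that higher always means more favorable: a rating r on a
#' negative-valence trait becomes (scale_min + scale_max) - r (on the default
#' 1-8 scale, 9 - r); ratings on positive traits are unchanged. The map is an
#' involution: applying it twice returns the input.
#'
#' @param rating Numeric rating(s) within the scale bounds.
#' @param valence `"positive"` or `"negative"` (recycled against `rating`).
#' @param scale_min,scale_max Rating-scale bounds.
#' @return Reverse-coded rating(s), same length as `rating`.
#' @export
#' @examples
#' reverse_code(1, "negative")  # 8
#' reverse_code(5, "positive")  # 5
reverse_code <- function(rating, valence, scale_min = 1L, scale_max = 8L) {
  if (any(rating < scale_min | rating > scale_max, na.rm = TRUE))
    stop("rating outside scale bounds [", scale_min, ", ", scale_max, "]")
  if (!all(valence %in% c("positive", "negative")))
    stop("valence must be 'positive' or 'negative'")
  ifelse(valence == "negative", (scale_min + scale_max) - rating, rating)
}

# Reverse-code a full per-trait vector/matrix of raw ratings onto the
# favorability scale (and back: the map is its own inverse).
to_favorability <- function(ratings, lexicon) {
  b <- scale_bounds(lexicon)
  neg <- lexicon$valence == "negative"
  if (is.matrix(ratings)) {
    stopifnot(ncol(ratings) == nrow(lexicon))
    ratings[, neg] <- (b[1] + b[2]) - ratings[, neg]
  } else {
    stopifnot(length(ratings) == nrow(lexicon))
    ratings[neg] <- (b[1] + b[2]) - ratings[neg]
  }
  ratings
}

new_similarity <- function(values, lexicon = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (!is.null(lexicon) && nrow(values) != nrow(lexicon))
    stop("similarity dimension (", nrow(values),
         ") does not match lexicon size (", nrow(lexicon), ")")
  if (max(abs(values - t(values))) > 1e-12) stop("similarity matrix must be symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  if (!is.null(lexicon)) dimnames(values) <- list(lexicon$label, lexicon$label)
  class(values) <- c("similarity_matrix", class(values))
  values
}

#' Block similarity over Big Five factors
#'
#' The coarse models' implicit generalization structure made explicit:
#' s(i, j) = 1 when traits i and j load on the same Big Five factor, 0
#' otherwise. Under this matrix (with factor-tied initial expectations) the
#' fine-granularity update reproduces the coarse factor-level update exactly,
#' which is used as an equivalence check in the test-suite.
#'
#' @param lexicon A `trait_lexicon`.
#' @return A symmetric 0/1 `similarity_matrix` with unit diagonal.
#' @export
block_similarity <- function(lexicon) {
  f <- lexicon$factor
  new_similarity(outer(f, f, "==") * 1, lexicon)
}

#' Empirical trait-trait similarity from a reference rating table
#'
#' Builds the fine-granularity models' generalization weights as pairwise
#' Pearson correlations between trait columns of a profiles-by-traits rating
#' table. Ratings are reverse-coded onto the favorability scale first so that
#' within-factor traits point in the same direction. Off-diagonal weights can
#' be shrunk toward zero; correlations are naturally signed (anti-correlated
#' traits generalize with opposite sign) and can be clipped at zero.
#'
#' @param rating_table Numeric matrix or data.frame, one row per rated profile,
#'   one column per trait (raw 1-8 scale, lexicon order). At least 3 rows.
#' @param lexicon A `trait_lexicon`.
#' @param shrinkage Weight in \[0, 1\]; off-diagonal entries are multiplied by
#'   `1 - shrinkage`. Default 0.
#' @param clip_negative When `TRUE`, negative correlations are set to 0.
#' @param reverse_coded Set `TRUE` if `rating_table` is already on the
#'   favorability scale.
#' @return A `similarity_matrix`; traits with zero variance get off-diagonal
#'   weights of 0 (with a warning).
#' @export
empirical_similarity <- function(rating_table, lexicon, shrinkage = 0,
                                 clip_negative = FALSE, reverse_coded = FALSE) {
  rating_table <- as.matrix(rating_table)
  if (nrow(rating_table) < 3L) stop("need at least 3 rating rows")
  if (ncol(rating_table) != nrow(lexicon))
    stop("rating_table must have one column per lexicon trait")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  if (!reverse_coded) rating_table <- to_favorability(rating_table, lexicon)
  zero_var <- apply(rating_table, 2, function(x) sd(x) == 0)
  s <- suppressWarnings(cor(rating_table))
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance trait column(s); their generalization ",
            "weights set to 0")
    s[zero_var, ] <- 0
    s[, zero_var] <- 0
  }
  s[is.na(s)] <- 0
  s <- s * (1 - shrinkage)
  if (clip_negative) s[s < 0] <- 0
  diag(s) <- 1
  new_similarity(s, lexicon)
}

#' Read / write lexicon and similarity files
#'
#' Plain-CSV interchange: the lexicon as columns `trait_id,label,factor,valence`
#' and the similarity matrix as a square CSV with trait labels as header
#' row/column.
#'
#' @param path File path.
#' @param lexicon A `trait_lexicon`.
#' @param scale_min,scale_max Scale bounds to attach on read.
#' @name lexicon_io
NULL

#' @rdname lexicon_io
#' @export
write_lexicon <- function(lexicon, path) {
  write.csv(as.data.frame(lexicon), path, row.names = FALSE)
  invisible(path)
}

#' @rdname lexicon_io
#' @export
read_lexicon <- function(path, scale_min = 1L, scale_max = 8L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trait_id", "label", "factor", "valence")
  if (!all(need %in% names(df)))
    stop("lexicon file must have columns: ", paste(need, collapse = ", "))
  build_default_lexicon(
    factor_counts = table(factor(df$factor, levels = unique(df$factor))),
    labels = df$label, scale_min = scale_min, scale_max = scale_max,
    strict = FALSE,
    positive_per_factor = tapply(df$valence == "positive",
                                 factor(df$factor, levels = unique(df$factor)), sum)
  ) -> lex
  # preserve the file's own factor/valence assignment, order and ids
  lex$factor <- df$factor
  lex$valence <- df$valence
  lex$trait_id <- df$trait_id
  lex
}

#' @rdname lexicon_io
#' @param sim A `similarity_matrix`.
#' @export
write_similarity <- function(sim, path) {
  write.csv(as.data.frame(unclass(sim)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname lexicon_io
#' @export
read_similarity <- function(path, lexicon = NULL) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  new_similarity(m, lexicon)
}
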