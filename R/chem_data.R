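## Compound ingestion, Tanimoto leader clustering and cluster-atomic
## cross-validation folds. Clusters are assigned to folds as whole units so
## that train and test sets occupy divergent chemical space.

#' Construct a sparse binary fingerprint matrix
#'
#' Rows are compounds, columns fingerprint bits. Any nonzero entry is coerced
#' to 1; explicit zeros are dropped.
#'
#' @param x a matrix, `Matrix::sparseMatrix()` or anything coercible to
#'   `dgCMatrix`.
#' @return a binary `dgCMatrix` with class attribute `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(x) {
  m <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  m <- drop0(m)
  m@x <- rep_len(1, length(m@x))
  m
}

#' Validate fingerprints for similarity computations
#'
#' @param fps fingerprint matrix.
#' @param forbid_empty error on all-zero rows (Tanimoto similarity is
#'   undefined for an empty fingerprint).
#' @return the validated matrix, invisibly.
#' @export
validate_fingerprints <- function(fps, forbid_empty = TRUE) {
  if (!methods::is(fps, "CsparseMatrix")) fps <- fingerprint_matrix(fps)
  if (length(fps@x) && any(fps@x != 1))
    stop("fingerprint matrix must be binary (all stored values 1)")
  if (forbid_empty && nrow(fps) > 0 && any(rowSums(fps) == 0))
    stop("fingerprint matrix contains all-zero rows; Tanimoto similarity is undefined")
  invisible(fps)
}

#' Bundle features, labels, clusters and folds
#'
#' @param features binary fingerprint matrix (`n x d`).
#' @param labels 0/1 activity labels, length `n` (1 = active).
#' @param cluster_id integer cluster memberships (0-based, contiguous),
#'   or `NULL` if not yet clustered.
#' @param fold_id integer fold memberships in `0..n_folds-1`, or `NULL`.
#' @return object of class `bioactivity_dataset`.
#' @export
bioactivity_dataset <- function(features, labels, cluster_id = NULL,
                                fold_id = NULL) {
  features <- fingerprint_matrix(features)
  n <- nrow(features)
  labels <- as.numeric(labels)
  if (length(labels) != n) stop("labels must have length nrow(features)")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (!is.null(cluster_id) && length(cluster_id) != n)
    stop("cluster_id must have length nrow(features)")
  if (!is.null(fold_id)) {
    if (length(fold_id) != n) stop("fold_id must have length nrow(features)")
    if (!is.null(cluster_id)) {
      spans <- tapply(fold_id, cluster_id, function(f) length(unique(f)))
      if (any(spans > 1)) stop("a cluster spans multiple folds")
    }
  }
  structure(
    list(features = features, labels = labels,
         cluster_id = if (is.null(cluster_id)) NULL else as.integer(cluster_id),
         fold_id = if (is.null(fold_id)) NULL else as.integer(fold_id)),
    class = "bioactivity_dataset")
}

#' @exportS3Method base::print
print.bioactivity_dataset <- function(x, ...) {
  cat(sprintf("<bioactivity_dataset> %d compounds x %d bits, active ratio %.3f\n",
              nrow(x$features), ncol(x$features), mean(x$labels)))
  if (!is.null(x$cluster_id))
    cat(sprintf("  %d clusters", length(unique(x$cluster_id))))
  if (!is.null(x$fold_id))
    cat(sprintf(", fold sizes: %s", paste(tabulate(x$fold_id + 1L), collapse = "/")))
  if (!is.null(x$cluster_id) || !is.null(x$fold_id)) cat("\n")
  invisible(x)
}

#' Tanimoto (Jaccard) similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|` over the set bits.
#'
#' @param a,b binary vectors (or sparse 1-row matrices) of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  a <- as.numeric(a) != 0
  b <- as.numeric(b) != 0
  if (length(a) != length(b)) stop("fingerprints have different lengths")
  u <- sum(a | b)
  if (u == 0) stop("Tanimoto similarity undefined: both fingerprints empty")
  sum(a & b) / u
}

## Tanimoto similarity of one fingerprint row against a set of leader rows;
## vectorized via sparse inner products.
.tanimoto_to_rows <- function(x, L, x_card, L_card) {
  inter <- as.numeric(L %*% x)
  inter / (x_card + L_card - inter)
}

#' Single-pass leader (sphere-exclusion) clustering
#'
#' Compounds are visited in a seeded random order; each is assigned to the
#' first existing leader with Tanimoto similarity at or above `threshold`,
#' otherwise it becomes a new leader. Leaders are therefore mutually less
#' similar than `threshold`, and every member is within the threshold sphere
#' of its leader.
#'
#' @param fps binary fingerprint matrix without all-zero rows.
#' @param threshold similarity threshold in (0, 1); default 0.6.
#' @param order_seed seed for the visiting-order shuffle; `NULL` keeps the
#'   input order.
#' @return integer vector of cluster ids, 0-based and contiguous in order of
#'   leader creation, aligned with the input rows.
#' @export
leader_cluster <- function(fps, threshold = 0.6, order_seed = NULL) {
  fps <- fingerprint_matrix(fps)
  n <- nrow(fps)
  if (n == 0) return(integer(0))
  validate_fingerprints(fps)
  .check_fraction(threshold, "threshold", 0, 1, lo_open = TRUE, hi_open = TRUE)
  ord <- seq_len(n)
  if (!is.null(order_seed))
    ord <- withr::with_seed(as.integer(order_seed), sample.int(n))
  card <- rowSums(fps)
  cluster <- integer(n)
  leader_rows <- integer(0)              # row indices of leaders
  for (i in ord) {
    if (length(leader_rows)) {
      sims <- .tanimoto_to_rows(fps[i, ], fps[leader_rows, , drop = FALSE],
                                card[i], card[leader_rows])
      hit <- which(sims >= threshold)
      if (length(hit)) {
        cluster[i] <- hit[1L] - 1L       # first leader in creation order
        next
      }
    }
    leader_rows <- c(leader_rows, i)
    cluster[i] <- length(leader_rows) - 1L
  }
  cluster
}

#' Assign clusters to cross-validation folds
#'
#' Whole clusters are assigned to folds (cluster-atomic). Clusters are sorted
#' by decreasing size and each is placed into the currently smallest fold;
#' ties among equally small folds are broken by a seeded random draw. This
#' greedy balancing keeps fold sizes close even for heavy-tailed cluster
#' size distributions.
#'
#' @param cluster_id integer cluster memberships (one per compound).
#' @param n_folds number of folds (default 5).
#' @param seed seed for tie-breaking.
#' @return integer fold id per compound, in `0..n_folds-1`.
#' @export
assign_folds <- function(cluster_id, n_folds = 5L, seed = 1L) {
  n_folds <- .check_count(n_folds, "n_folds", min = 2L)
  cluster_id <- as.integer(cluster_id)
  if (!length(cluster_id)) return(integer(0))
  sizes <- table(cluster_id)
  ids <- as.integer(names(sizes))
  if (length(ids) < n_folds)
    warning("fewer clusters than folds; some folds will be empty")
  ord <- order(-as.integer(sizes), ids)  # descending size, stable by id
  fold_of_cluster <- integer(length(ids))
  names(fold_of_cluster) <- as.character(ids)
  withr::with_seed(as.integer(seed), {
    fold_sizes <- numeric(n_folds)
    for (k in ord) {
      cand <- which(fold_sizes == min(fold_sizes))
      pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      fold_of_cluster[k] <- pick - 1L
      fold_sizes[pick] <- fold_sizes[pick] + as.integer(sizes[k])
    }
  })
  unname(fold_of_cluster[as.character(cluster_id)])
}

#' Train/validation/test split over five folds
#'
#' One fold validates, one tests, the remaining three train.
#'
#' @param valid_fold,test_fold distinct fold indices in `0..n_folds-1`.
#' @param n_folds total number of folds (default 5).
#' @return object of class `fold_split` with `train_folds`, `valid_fold`,
#'   `test_fold`.
#' @export
make_split <- function(valid_fold, test_fold, n_folds = 5L) {
  n_folds <- .check_count(n_folds, "n_folds", min = 3L)
  valid_fold <- .check_count(valid_fold, "valid_fold", min = 0L)
  test_fold <- .check_count(test_fold, "test_fold", min = 0L)
  if (valid_fold >= n_folds || test_fold >= n_folds)
    stop("fold indices must lie in 0..", n_folds - 1L)
  if (valid_fold == test_fold)
    stop("valid_fold and test_fold must differ")
  structure(
    list(train_folds = setdiff(seq_len(n_folds) - 1L, c(valid_fold, test_fold)),
         valid_fold = valid_fold, test_fold = test_fold, n_folds = n_folds),
    class = "fold_split")
}

#' @exportS3Method base::print
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> train {%s} | valid %d | test %d\n",
              paste(x$train_folds, collapse = ","), x$valid_fold, x$test_fold))
  invisible(x)
}

## internal: row indices of a dataset belonging to a split role
.split_idx <- function(data, split, role = c("train", "valid", "test")) {
  role <- match.arg(role)
  if (is.null(data$fold_id)) stop("dataset has no fold assignment")
  folds <- switch(role, train = split$train_folds,
                  valid = split$valid_fold, test = split$test_fold)
  which(data$fold_id %in% folds)
}

#' Read a sparse feature matrix with aligned labels
#'
#' Features in Matrix Market coordinate format (1-based indices); any stored
#' value is coerced to binary presence. Labels as a one-column text file
#' aligned by row order.
#'
#' @param mtx_path path to the `.mtx` file.
#' @param labels_path path to the label file (one 0/1 value per line).
#' @return a [bioactivity_dataset()] without cluster or fold assignments.
#' @export
read_feature_mtx <- function(mtx_path, labels_path) {
  if (!file.exists(mtx_path)) stop("no such file: ", mtx_path)
  if (!file.exists(labels_path)) stop("no such file: ", labels_path)
  m <- fingerprint_matrix(Matrix::readMM(mtx_path))
  y <- scan(labels_path, what = numeric(), quiet = TRUE)
  bioactivity_dataset(m, y)
}

#' Write a dataset as Matrix Market features plus label file
#'
#' @param data a [bioactivity_dataset()].
#' @param mtx_path,labels_path output paths.
#' @return invisibly, the paths written.
#' @export
write_feature_mtx <- function(data, mtx_path, labels_path) {
  Matrix::writeMM(data$features, mtx_path)
  writeLines(format(data$labels, trim = TRUE), labels_path)
  invisible(c(mtx_path, labels_path))
}

#' Export / import a cluster-and-fold split table
#'
#' Tab-separated with columns `compound_index` (1-based row index),
#' `cluster_id`, `fold_id`.
#'
#' @param data a clustered, folded [bioactivity_dataset()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_split_table <- function(data, path) {
  if (is.null(data$cluster_id) || is.null(data$fold_id))
    stop("dataset must carry cluster_id and fold_id")
  dt <- data.table::data.table(compound_index = seq_along(data$labels),
                               cluster_id = data$cluster_id,
                               fold_id = data$fold_id)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_split_table
#' @export
read_split_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("compound_index", "cluster_id", "fold_id")
  if (!all(need %in% names(dt))) stop("split table missing columns: ",
                                      paste(setdiff(need, names(dt)), collapse = ", "))
  dt[order(dt$compound_index)]
}

#' Default SMILES fingerprinter (OpenBabel ECFP6)
#'
#' Returns a function mapping one SMILES string to the 0-based indices of its
#' set bits in an `n_bits`-wide space, or `NULL` for an unparsable structure.
#' Radius-3 circular (ECFP6) fingerprints are computed by OpenBabel via
#' ChemmineOB (native fold 4096 bits) and placed into the requested bit space
#' by index modulo `n_bits`.
#'
#' @param n_bits width of the target bit space (default 32768).
#' @return a `function(smiles) -> integer bit indices or NULL`.
#' @export
ob_ecfp6_fingerprinter <- function(n_bits = 32768L) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required for SMILES featurization")
  force(n_bits)
  function(smiles) {
    fp <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
      v <- ChemmineOB::fingerprint_OB(mol, "ECFP6")
      if (sum(v) == 0) NULL else (which(as.numeric(v) != 0) - 1L) %% n_bits
    }, error = function(e) NULL)
    fp
  }
}

#' Load a compound activity table and featurize it
#'
#' Reads a delimited text table (comma or tab, autodetected, header
#' required), computes hashed circular fingerprints for each SMILES, and
#' derives binary activity labels. When `pic50_threshold` is given the label
#' column is interpreted as continuous pIC50 and a compound is active iff
#' `pIC50 >= pic50_threshold`; otherwise the label column must already be
#' binary. Rows with unparsable structures, or whose fingerprints come out
#' all-zero, are dropped with a warning.
#'
#' @param path path to the table.
#' @param smiles_column,label_column column names.
#' @param pic50_threshold optional activity threshold on the pIC50 scale.
#' @param n_bits fingerprint width (default 32768).
#' @param fingerprinter a `function(smiles)` returning 0-based bit indices or
#'   `NULL`; defaults to [ob_ecfp6_fingerprinter()].
#' @return a [bioactivity_dataset()].
#' @export
load_compound_table <- function(path, smiles_column, label_column,
                                pic50_threshold = NULL, n_bits = 32768L,
                                fingerprinter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  for (col in c(smiles_column, label_column))
    if (!col %in% names(tab)) stop("missing column: ", col)
  if (is.null(fingerprinter)) fingerprinter <- ob_ecfp6_fingerprinter(n_bits)

  bits <- lapply(tab[[smiles_column]], fingerprinter)
  bad <- vapply(bits, is.null, logical(1))
  if (any(bad))
    warning(sum(bad), " row(s) skipped: unparsable or empty structure")
  keep <- which(!bad)
  if (!length(keep)) stop("no valid structures in table")
  bits <- bits[keep]
  i <- rep(seq_along(bits), lengths(bits))
  j <- unlist(bits) + 1L
  fps <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(bits), n_bits))
  lab <- tab[[label_column]][keep]
  y <- if (is.null(pic50_threshold)) as.numeric(lab)
       else as.numeric(as.numeric(lab) >= pic50_threshold)
  bioactivity_dataset(fps, y)
}
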