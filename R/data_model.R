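# Core domain containers: the interaction matrix, compound and indication
# metadata tables, and the analysis configuration. All identifiers are
# whitespace-trimmed and case-folded on ingest; validation is strict --
# a malformed matrix or a psychoactive listed as an approved treatment is
# an error, never silently repaired.

CHEM_CLASSES <- c("amphetamine", "cathinone", "phenethylamine",
                  "tryptamine", "cannabinoid", "other", "none")

#' Construct a validated compound-by-protein interaction matrix
#'
#' The interaction matrix holds one real-valued proteome-wide interaction
#' signature per compound (rows = compounds, columns = proteins). It is the
#' signature universe against which all similarity comparisons are made.
#'
#' @param scores numeric matrix with compound ids as rownames and protein
#'   ids as colnames.
#' @return the matrix, with class `interaction_matrix`, ids normalized
#'   (trimmed, case-folded).
#' @examples
#' m <- interaction_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("c1", "c2"), c("p1", "p2", "p3"))))
#' @export
interaction_matrix <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("scores must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("scores must carry compound rownames and protein colnames", call. = FALSE)
  }
  rownames(scores) <- norm_id(rownames(scores))
  colnames(scores) <- norm_id(colnames(scores))
  validate_interaction_matrix(scores)
  class(scores) <- c("interaction_matrix", class(scores))
  scores
}

validate_interaction_matrix <- function(scores) {
  dup_r <- rownames(scores)[duplicated(rownames(scores))]
  if (length(dup_r)) {
    stop("duplicate compound id(s): ", paste(unique(dup_r), collapse = ", "),
         call. = FALSE)
  }
  dup_c <- colnames(scores)[duplicated(colnames(scores))]
  if (length(dup_c)) {
    stop("duplicate protein id(s): ", paste(unique(dup_c), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(scores), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("missing/non-finite interaction score at compound '%s', protein '%s'",
                 rownames(scores)[bad[1, 1]], colnames(scores)[bad[1, 2]]),
         call. = FALSE)
  }
  invisible(scores)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d compounds x %d proteins\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Read an interaction matrix from disk
#'
#' Two dialects are supported: a TSV with the compound id in the first
#' column and protein ids in the header row, and Matrix Market
#' (coordinate or array) with sidecar plain-text label files
#' (`<path>.rows`, `<path>.cols`, one id per line).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"matrix-market"`.
#' @return an [interaction_matrix()].
#' @seealso [save_matrix()]
#' @export
load_matrix <- function(path, dialect = c("tsv", "matrix-market")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                            colClasses = "character", quote = "", comment.char = "")
    if (ncol(df) < 2) stop("matrix TSV needs an id column plus scores", call. = FALSE)
    ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    mm <- Matrix::readMM(path)
    m <- as.matrix(mm)
    rows <- readLines(paste0(path, ".rows"))
    cols <- readLines(paste0(path, ".cols"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
      stop("sidecar label files do not match matrix dimensions", call. = FALSE)
    }
    dimnames(m) <- list(rows, cols)
  }
  interaction_matrix(m)
}

#' Write an interaction matrix to disk
#'
#' @param matrix an [interaction_matrix()] (or labelled numeric matrix).
#' @param path destination file path.
#' @param dialect `"tsv"` or `"matrix-market"` (writes `<path>.rows` /
#'   `<path>.cols` sidecars).
#' @return `path`, invisibly.
#' @export
save_matrix <- function(matrix, path, dialect = c("tsv", "matrix-market")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- data.frame(compound_id = rownames(matrix), unclass(matrix),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(matrix), sparse = TRUE), path)
    writeLines(rownames(matrix), paste0(path, ".rows"))
    writeLines(colnames(matrix), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read and cross-validate compound and indication metadata
#'
#' Compounds arrive as a TSV with columns `compound_id`, `name`, `smiles`,
#' `is_psychoactive`, `chem_class`; indications as a TSV with columns
#' `mesh_id`, `name`, `is_mental_health`, `approved_compound_ids`
#' (semicolon-joined). Two invariants are enforced at load: an approved
#' treatment is never a flagged psychoactive (the platform predicts
#' psychoactives *from* approved non-psychoactive drugs, so a psychoactive
#' in an approved set would contaminate the prediction direction), and every
#' approved id must exist in the interaction matrix.
#'
#' @param compounds_path,indications_path TSV file paths.
#' @param matrix the [interaction_matrix()] the ids must resolve against.
#' @return list with elements `compounds` and `indications` (see
#'   [compound_table()] and [indication_table()]).
#' @export
load_metadata <- function(compounds_path, indications_path, matrix) {
  cmp <- utils::read.table(compounds_path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", na.strings = c("NA", ""))
  compounds <- compound_table(
    compound_id = cmp$compound_id,
    name = cmp$name,
    smiles = cmp$smiles,
    is_psychoactive = as.logical(cmp$is_psychoactive),
    chem_class = ifelse(is.na(cmp$chem_class), "none", cmp$chem_class)
  )
  ind <- utils::read.table(indications_path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", na.strings = c("NA", ""))
  approved <- strsplit(ifelse(is.na(ind$approved_compound_ids), "",
                              ind$approved_compound_ids), ";", fixed = TRUE)
  indications <- indication_table(
    mesh_id = ind$mesh_id,
    name = ind$name,
    is_mental_health = as.logical(ind$is_mental_health),
    approved = approved,
    compounds = compounds,
    matrix = matrix
  )
  list(compounds = compounds, indications = indications)
}

#' Build a validated compound metadata table
#'
#' @param compound_id,name character vectors.
#' @param smiles optional structure strings (NA allowed).
#' @param is_psychoactive logical vector.
#' @param chem_class one of amphetamine, cathinone, phenethylamine,
#'   tryptamine, cannabinoid, other, none. Any class other than `"none"`
#'   implies a psychoactive flag (the six labels partition the psychoactive
#'   set; `"none"` marks non-psychoactives).
#' @return data.frame of class `compound_table`.
#' @export
compound_table <- function(compound_id, name = compound_id, smiles = NA_character_,
                           is_psychoactive = FALSE, chem_class = "none") {
  n <- length(compound_id)
  df <- data.frame(
    compound_id = norm_id(compound_id),
    name = rep_len(as.character(name), n),
    smiles = rep_len(as.character(smiles), n),
    is_psychoactive = rep_len(as.logical(is_psychoactive), n),
    chem_class = rep_len(as.character(chem_class), n),
    stringsAsFactors = FALSE
  )
  dup <- df$compound_id[duplicated(df$compound_id)]
  if (length(dup)) {
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$is_psychoactive)) stop("is_psychoactive must be TRUE/FALSE", call. = FALSE)
  bad <- setdiff(unique(df$chem_class), CHEM_CLASSES)
  if (length(bad)) {
    stop("unknown chem_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  viol <- df$chem_class != "none" & !df$is_psychoactive
  if (any(viol)) {
    stop("chem_class other than 'none' requires is_psychoactive = TRUE: ",
         paste(df$compound_id[viol], collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$compound_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("compound_table", "data.frame")
  df
}

#' Build a validated indication metadata table
#'
#' @param mesh_id,name character vectors (MeSH descriptor ids and names).
#' @param is_mental_health logical; mental-health (MeSH F03, plus the
#'   epilepsy subtree pooled with it) versus all other indications. The flag
#'   is curated input, not computed here.
#' @param approved list of character vectors of approved compound ids
#'   (may be empty; such indications are kept but marked unusable).
#' @param compounds optional [compound_table()] for the psychoactive check.
#' @param matrix optional [interaction_matrix()] for the existence check.
#' @return data.frame of class `indication_table` with list-column
#'   `approved` and logical `usable`.
#' @export
indication_table <- function(mesh_id, name = mesh_id, is_mental_health = FALSE,
                             approved = list(), compounds = NULL, matrix = NULL) {
  n <- length(mesh_id)
  if (length(approved) == 0) approved <- rep(list(character()), n)
  approved <- lapply(approved, function(a) unique(norm_id(a[nzchar(trimws(a))])))
  df <- data.frame(
    mesh_id = norm_id(mesh_id),
    name = rep_len(as.character(name), n),
    is_mental_health = rep_len(as.logical(is_mental_health), n),
    stringsAsFactors = FALSE
  )
  dup <- df$mesh_id[duplicated(df$mesh_id)]
  if (length(dup)) {
    stop("duplicate indication id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$is_mental_health)) stop("is_mental_health must be TRUE/FALSE", call. = FALSE)
  df$approved <- approved
  if (!is.null(compounds)) {
    psycho <- compounds$compound_id[compounds$is_psychoactive]
    for (i in seq_len(n)) {
      hit <- intersect(df$approved[[i]], psycho)
      if (length(hit)) {
        stop(sprintf("psychoactive compound '%s' listed as approved for indication '%s'",
                     hit[1], df$mesh_id[i]), call. = FALSE)
      }
    }
  }
  if (!is.null(matrix)) {
    known <- rownames(matrix)
    for (i in seq_len(n)) {
      miss <- setdiff(df$approved[[i]], known)
      if (length(miss)) {
        stop(sprintf("approved compound '%s' (indication '%s') absent from interaction matrix",
                     miss[1], df$mesh_id[i]), call. = FALSE)
      }
    }
  }
  df$usable <- lengths(df$approved) > 0
  ord <- order(df$mesh_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("indication_table", "data.frame")
  df
}

#' Analysis configuration
#'
#' Defaults mirror the study design: TopX cutoffs 10/25/40/100 with
#' per-TopX minimum consensus thresholds 2/3/4/6 for association counting,
#' and 1000 randomized-control replicates.
#'
#' @param topx_values integer vector of TopX list lengths.
#' @param association_thresholds named integer vector mapping TopX to the
#'   minimum consensus count a shared psychoactive must reach in both
#'   indications of a pair.
#' @param n_randomizations replicates for each randomized control.
#' @param seed integer seed governing all randomness.
#' @param similarity_metric only `"rmsd"` is implemented.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(topx_values = c(10L, 25L, 40L, 100L),
                            association_thresholds = c("10" = 2L, "25" = 3L,
                                                       "40" = 4L, "100" = 6L),
                            n_randomizations = 1000L,
                            seed = 1L,
                            similarity_metric = "rmsd") {
  topx_values <- as.integer(topx_values)
  if (any(topx_values < 1)) stop("topx_values must be positive", call. = FALSE)
  thr <- as.integer(association_thresholds)
  names(thr) <- names(association_thresholds)
  if (is.null(names(thr)) || any(!nzchar(names(thr)))) {
    stop("association_thresholds must be named by TopX", call. = FALSE)
  }
  if (!all(names(thr) %in% as.character(topx_values))) {
    stop("every TopX in association_thresholds must appear in topx_values",
         call. = FALSE)
  }
  if (any(thr < 1)) stop("association thresholds must be >= 1", call. = FALSE)
  if (!identical(similarity_metric, "rmsd")) {
    stop("only the 'rmsd' similarity metric is implemented", call. = FALSE)
  }
  n_randomizations <- as.integer(n_randomizations)
  if (n_randomizations < 1) stop("n_randomizations must be positive", call. = FALSE)
  structure(
    list(topx_values = topx_values,
         association_thresholds = thr,
         n_randomizations = n_randomizations,
         seed = as.integer(seed),
         similarity_metric = similarity_metric),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML-style key-value file
#'
#' @param path file path; keys mirror the [analysis_config()] arguments
#'   (`association_thresholds` as a TopX-keyed map). Missing keys fall back
#'   to the defaults.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- analysis_config()
  thr <- if (!is.null(y$association_thresholds)) {
    unlist(y$association_thresholds)
  } else defaults$association_thresholds
  analysis_config(
    topx_values = y$topx_values %||% defaults$topx_values,
    association_thresholds = thr,
    n_randomizations = y$n_randomizations %||% defaults$n_randomizations,
    seed = y$seed %||% defaults$seed,
    similarity_metric = y$similarity_metric %||% defaults$similarity_metric
  )
}
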