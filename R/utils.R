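# Internal helpers shared across modules.

# Coerce a counts tibble (first column = feature id, remaining columns =
# subjects) to a numeric matrix with feature ids as rownames.
counts_to_matrix <- function(counts, id_col = 1L) {
  if (is.matrix(counts)) return(counts)
  stopifnot(is.data.frame(counts), ncol(counts) >= 2L)
  ids <- as.character(counts[[id_col]])
  m <- as.matrix(counts[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_counts <- function(m, id_name = "mirna_id") {
  tibble::as_tibble(m, rownames = id_name)
}

# Validate a CountMatrix contract: unique ids, non-negative counts.
validate_counts <- function(m, call = rlang::caller_env()) {
  if (anyDuplicated(rownames(m))) {
    abort("Duplicate feature identifiers in count matrix.", call = call)
  }
  if (anyDuplicated(colnames(m))) {
    abort("Duplicate subject identifiers in count matrix.", call = call)
  }
  if (anyNA(m) || any(m < 0)) {
    abort("Counts must be non-negative and non-missing.", call = call)
  }
  invisible(m)
}

# Two-level group factor with "control" as reference and "case" as positive.
as_group <- function(group, call = rlang::caller_env()) {
  g <- as.character(group)
  lev <- unique(g)
  if (length(lev) != 2L && !all(lev %in% c("case", "control"))) {
    abort("`group` must contain exactly two classes.", call = call)
  }
  if (all(lev %in% c("case", "control"))) {
    factor(g, levels = c("control", "case"))
  } else {
    factor(g, levels = sort(lev))
  }
}

# 0/1 coding of the positive (second-level) class.
group_to_y <- function(group) as.integer(as_group(group)) - 1L

# Derive independent substream seeds below 2^31 from a master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

log2p1 <- function(x) log2(x + 1)

clip01 <- function(x) pmin(1, pmax(0, x))
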