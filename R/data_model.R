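#' Construct a multi-trait multi-environment count dataset
#'
#' Validates and indexes a long-format table of count phenotypes, one row per
#' (environment, line, replicate, trait) combination.  Counts must be
#' non-negative integers; combinations must be unique; every declared line must
#' appear in at least one environment.
#'
#' @param records data.frame with columns `env`, `line`, `rep`, `trait`,
#'   `count` (labels may be character, factor or integer).
#' @param env_ids,line_ids,trait_ids optional label vectors fixing level order;
#'   defaults to the sorted unique labels found in `records`.
#' @return An object of class `count_dataset`: the validated records plus the
#'   label vectors.
#' @export
count_dataset <- function(records, env_ids = NULL, line_ids = NULL,
                          trait_ids = NULL) {
  need <- c("env", "line", "rep", "trait", "count")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("phenotype records lack column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[need]
  y <- records$count
  if (!is.numeric(y))
    stop("counts must be numeric, got ", class(y)[1])
  bad <- which(is.na(y) | y < 0 | y != floor(y))
  if (length(bad))
    stop("counts must be non-negative integers; first offending row: ",
         bad[1], " (count = ", y[bad[1]], ")")
  records$count <- as.integer(y)
  key <- paste(records$env, records$line, records$rep, records$trait,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (env, line, rep, trait) combination at row ",
         which(duplicated(key))[1])
  as_ids <- function(x) {
    if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
  }
  if (is.null(env_ids)) env_ids <- as_ids(records$env)
  if (is.null(line_ids)) line_ids <- as_ids(records$line)
  if (is.null(trait_ids)) trait_ids <- as_ids(records$trait)
  for (col in c("env", "line", "trait")) records[[col]] <- as.character(records[[col]])
  if (!all(records$trait %in% trait_ids))
    stop("record trait not among declared traits: ",
         setdiff(records$trait, trait_ids)[1])
  if (!all(records$env %in% env_ids))
    stop("record environment not among declared environments")
  if (!all(records$line %in% line_ids))
    stop("record line not among declared lines")
  if (!all(line_ids %in% records$line))
    stop("declared line(s) never observed in any environment: ",
         setdiff(line_ids, records$line)[1])
  structure(
    list(records = records, env_ids = env_ids, line_ids = line_ids,
         trait_ids = trait_ids),
    class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("count_dataset:", nrow(x$records), "records |",
      length(x$env_ids), "environments x", length(x$line_ids), "lines x",
      length(x$trait_ids), "traits\n")
  invisible(x)
}

#' Read a long-format phenotype table
#'
#' Reads a delimited text file (comma- or tab-separated, chosen from the file
#' extension unless `sep` is given) with one row per environment, line,
#' replicate and trait, and validates it into a [count_dataset()].
#'
#' @param path file path.
#' @param schema named character vector mapping the internal names
#'   `env`, `line`, `rep`, `trait`, `count` to the file's column names.
#' @param sep field separator; default `","` for `.csv`, `"\t"` otherwise.
#' @return A `count_dataset`.
#' @examples
#' f <- system.file("extdata", "toy_phenotypes.csv", package = "bpmtme")
#' load_phenotypes(f)
#' @export
load_phenotypes <- function(path,
                            schema = c(env = "env", line = "line",
                                       rep = "rep", trait = "trait",
                                       count = "count"),
                            sep = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("env", "line", "rep", "trait", "count")
  schema <- schema[need]
  if (anyNA(schema)) stop("schema must map all of: ", paste(need, collapse = ", "))
  miss <- setdiff(unname(schema), names(df))
  if (length(miss))
    stop("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  out <- df[unname(schema)]
  names(out) <- need
  count_dataset(out)
}

#' Collapse replicates to per-cell sums
#'
#' Sums counts over replicates within each (environment, line, trait) cell and
#' records the number of replicates per cell.  Model fitting operates on these
#' sums; the intercepts absorb the replicate-count scale, so no offset is
#' applied.  Every retained cell must carry all declared traits.
#'
#' @param data a [count_dataset()].
#' @return An object of class `collapsed_counts`: data.frame `cells` with
#'   columns `env`, `line`, `trait`, `sum`, `K`, plus the label vectors.
#' @export
collapse_replicates <- function(data) {
  stopifnot(inherits(data, "count_dataset"))
  rec <- data$records
  agg <- stats::aggregate(count ~ env + line + trait, data = rec, FUN = sum)
  nrep <- stats::aggregate(count ~ env + line + trait, data = rec,
                           FUN = length)
  agg$K <- nrep$count[match(paste(agg$env, agg$line, agg$trait),
                            paste(nrep$env, nrep$line, nrep$trait))]
  names(agg)[names(agg) == "count"] <- "sum"
  L <- length(data$trait_ids)
  ntr <- table(paste(agg$env, agg$line, sep = "\r"))
  if (any(ntr != L)) {
    bad <- names(ntr)[ntr != L][1]
    bad <- strsplit(bad, "\r", fixed = TRUE)[[1]]
    stop("cell (env = ", bad[1], ", line = ", bad[2],
         ") does not carry all ", L, " traits")
  }
  kchk <- tapply(agg$K, paste(agg$env, agg$line, sep = "\r"), unique)
  agg <- agg[order(match(agg$env, data$env_ids),
                   match(agg$line, data$line_ids),
                   match(agg$trait, data$trait_ids)), , drop = FALSE]
  rownames(agg) <- NULL
  structure(
    list(cells = agg, env_ids = data$env_ids, line_ids = data$line_ids,
         trait_ids = data$trait_ids),
    class = "collapsed_counts")
}

#' @export
print.collapsed_counts <- function(x, ...) {
  cat("collapsed_counts:", nrow(x$cells) / length(x$trait_ids),
      "env-line cells |", length(x$env_ids), "environments x",
      length(x$line_ids), "lines x", length(x$trait_ids), "traits\n")
  invisible(x)
}

#' Restrict a dataset to a subset of traits or cells
#'
#' `subset_traits` keeps only the named traits (used to fit the univariate
#' BPME model trait by trait).  `drop_cells` removes whole (env, line) cells,
#' which is how CV1 masking excludes test cells from training.
#'
#' @param data a `collapsed_counts` object.
#' @param traits character vector of trait labels to keep.
#' @return A `collapsed_counts` object.
#' @export
subset_traits <- function(data, traits) {
  stopifnot(inherits(data, "collapsed_counts"))
  if (!all(traits %in% data$trait_ids))
    stop("unknown trait(s): ", paste(setdiff(traits, data$trait_ids),
                                     collapse = ", "))
  cells <- data$cells[data$cells$trait %in% traits, , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, env_ids = data$env_ids,
                 line_ids = data$line_ids, trait_ids = traits),
            class = "collapsed_counts")
}

#' @rdname subset_traits
#' @param mask data.frame with columns `env`, `line` naming the cells to drop.
#' @export
drop_cells <- function(data, mask) {
  stopifnot(inherits(data, "collapsed_counts"))
  key <- paste(data$cells$env, data$cells$line, sep = "\r")
  drop <- key %in% paste(mask$env, mask$line, sep = "\r")
  cells <- data$cells[!drop, , drop = FALSE]
  left <- unique(cells$line)
  if (!all(data$line_ids %in% left))
    stop("masking would leave line(s) unobserved in every environment: ",
         setdiff(data$line_ids, left)[1])
  rownames(cells) <- NULL
  structure(list(cells = cells, env_ids = data$env_ids,
                 line_ids = data$line_ids, trait_ids = data$trait_ids),
            class = "collapsed_counts")
}
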