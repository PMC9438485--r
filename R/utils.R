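## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

## Deterministic stage seeds derived from one master seed.  Kept strictly
## below 2^31 so they are valid R integer seeds.
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  stage_num <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(master_seed) * 48271 + stage_num * 7919) %% 2147483647)
}

## TSV writers: every tabular output of the package goes through this so
## formats stay consistent and byte-reproducible.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## group -> character vector of sample ids, validated against the matrix
resolve_group <- function(geno, group) {
  if (is.null(group) || length(group) == 0L)
    stop_input("empty sample group")
  miss <- setdiff(group, rownames(geno))
  if (length(miss))
    stop_input("samples not present in genotype matrix: ",
               paste(utils::head(miss, 5L), collapse = ", "))
  group
}
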