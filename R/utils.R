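# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards.  All seeded entry points funnel through here so a
# fixed seed gives bit-identical results without clobbering the session RNG.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Provenance comment line prepended to CLI output tables.
.provenanceHeader <- function(seed = NA, inputs = character(0)) {
  ver <- as.character(utils::packageVersion("isoscope"))
  hashes <- if (length(inputs) > 0) {
    md5 <- tools::md5sum(inputs)
    paste(sprintf("%s=%s", basename(names(md5)), unname(md5)),
          collapse = ",")
  } else ""
  sprintf("# isoscope %s; seed=%s; inputs: %s", ver, as.character(seed),
          hashes)
}

# Write a data.frame as TSV with an optional provenance header comment.
.writeTsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
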