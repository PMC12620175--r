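# shared internal utilities

# gyromagnetic ratio of 1H over 2*pi, Hz/T
.GAMMA_BAR <- 42.577e6

# evaluate `code` under a temporary RNG seed, restoring global RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# derive a reproducible integer sub-seed from a base seed and a tag
.sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

.rms <- function(x) sqrt(mean(Re(x * Conj(x))))

# canonical JSON (recursively name-sorted) and its md5, used for config
# provenance hashes
.canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v))
      v <- lapply(v[order(names(v))], sort_rec)
    else if (is.list(v)) v <- lapply(v, sort_rec)
    v
  }
  jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(.canonical_json(x)), f)
  unname(tools::md5sum(f))
}
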