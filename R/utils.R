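# internal helpers shared across modules

# flatten N x 3 coordinates residue-major: x1,y1,z1,x2,y2,z2,...
flatten_coords <- function(x) as.vector(t(x))

unflatten_coords <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

.sigdyn_cache <- new.env(parent = emptyenv())

# BLOSUM62 substitution matrix, loaded once from Biostrings
blosum62 <- function() {
  if (is.null(.sigdyn_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sigdyn_cache$BLOSUM62 <- e$BLOSUM62
  }
  .sigdyn_cache$BLOSUM62
}

# population variance (divisor n)
pop_var <- function(x) mean((x - mean(x))^2)

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
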