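# Internal helpers: classed conditions and reproducible RNG scoping.

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dyadgroom_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

schema_error <- function(msg, ...) stop_with("dyadgroom_schema_error", msg, ...)
config_error <- function(msg, ...) stop_with("dyadgroom_config_error", msg, ...)
key_error    <- function(msg, ...) stop_with("dyadgroom_key_error", msg, ...)
domain_error <- function(msg, ...) stop_with("dyadgroom_domain_error", msg, ...)
data_error   <- function(msg, ...) stop_with("dyadgroom_data_error", msg, ...)

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
# Each randomized stage derives its own stream from a master seed by a fixed
# offset so that adding a stage never shifts the draws of existing ones.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error("'%s' must be a single finite number", name)
  invisible(x)
}

# All N*(N-1) ordered pairs of ids, in deterministic (actor, recipient) order.
ordered_pairs <- function(ids) {
  g <- expand.grid(recipient_id = ids, actor_id = ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[g$actor_id != g$recipient_id, c("actor_id", "recipient_id")]
  g <- g[order(g$actor_id, g$recipient_id), ]
  rownames(g) <- NULL
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
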