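# Internal helpers shared across modules.

stop_bindmode <- function(msg, class) {
  abort(msg, class = c(class, "bindmode_error"))
}

# Vector cross product.
cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

vnorm <- function(v) sqrt(sum(v^2))

# Deterministic per-replica sub-seed; kept below 2^31.
replica_seed <- function(master_seed, replica) {
  as.integer((as.double(master_seed) * 48271 + replica * 100003) %% 2147483647)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%theni%` <- function(x, y) if (length(x) == 0L) y else x
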