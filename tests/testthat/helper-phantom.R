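# Shared fixtures built in code. The small phantom keeps unit tests fast;
# registration-based acceptance tests use the default phantom and cache the
# expensive run in an environment shared across test files.

small_spec <- function(...) {
  phantom_spec(shape = c(48L, 48L, 24L), spacing = c(2, 2, 5),
               semiaxes_mm = c(35, 38, 50), ...)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_phantom <- function() cached("default_phantom",
                                     generate_phantom(phantom_spec()))

# Full registration of the default phantom: the expensive shared fixture
# behind the strain-recovery and volume-consistency checks.
default_registration <- function() cached("default_registration", {
  ph <- default_phantom()
  suppressWarnings(register_pair(ph$ee$ct, ph$ei$ct, ph$ei$mask,
                                 registration_config(),
                                 mask_ee = ph$ee$mask))
})
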