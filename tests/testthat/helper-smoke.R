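# The smoke-scale study bundle is expensive (a few minutes); compute it
# once per test session and share it across test files.
.smoke_cache <- new.env(parent = emptyenv())

get_smoke_bundle <- function() {
  if (is.null(.smoke_cache$bundle))
    .smoke_cache$bundle <- smoke_study(base_seed = 1)
  .smoke_cache$bundle
}
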