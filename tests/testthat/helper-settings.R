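# Report every failure instead of stopping the run at the reporter's
# default cap: some acceptance blocks document known unreproduced published
# values and must not mask the rest of the suite.
options(testthat.progress.max_fails = 1000L)
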