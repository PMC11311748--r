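# Quiet structured logging during tests; warnings/errors still surface
# through the condition system.
old_opts <- options(formulanet.log_level = "silent")
withr::defer(options(old_opts), teardown_env())
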