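# The power-grid reproduction test reports every deviating cell; make
# sure the reporter never aborts the run before the remaining files.
options(testthat.progress.max_fails = Inf)
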