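# run every file to completion even when acceptance anchors fail
options(testthat.progress.max_fails = 1000)
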