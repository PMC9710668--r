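>NP_900001.1 Homo sapiens SYNX1 (synthetic)
MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRV
>NP_900002.1 Mus musculus Synx1 (synthetic)
MKTAYIAKQ-QISFVKSHFSRQLEERLGLIEVQAPILSRV
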