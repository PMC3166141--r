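S3ab:
- S3a
- S3b
S2de:
- S2d
- S2e

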