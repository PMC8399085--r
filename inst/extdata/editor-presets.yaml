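# Editor presets: PAM matched immediately 3' of the protospacer on the
# protospacer strand; window positions are 1-based from the protospacer 5'
# (PAM-distal) end; conversion is source -> product.
spcas9-abemax:
  pam: NGG
  protospacer_len: 20
  window_lo: 4
  window_hi: 8
  source: A
  product: G
spcas9-abe7.10:
  pam: NGG
  protospacer_len: 20
  window_lo: 4
  window_hi: 8
  source: A
  product: G
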