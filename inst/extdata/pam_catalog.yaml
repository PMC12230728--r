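# PAM catalog: user-editable. Each entry: name, IUPAC pattern, orientation
# (three_prime = PAM downstream of the spacer, Cas9 convention;
#  five_prime  = PAM upstream, Cpf1/Cas12a convention).
- name: NGG
  pattern: NGG
  orientation: three_prime
- name: NRG
  pattern: NRG
  orientation: three_prime
- name: NAG
  pattern: NAG
  orientation: three_prime
- name: NNGRRT
  pattern: NNGRRT
  orientation: three_prime
- name: TTTN
  pattern: TTTN
  orientation: five_prime
- name: TTTV
  pattern: TTTV
  orientation: five_prime
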