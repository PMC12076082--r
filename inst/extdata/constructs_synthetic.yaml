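constructs:
- name: LCD2-CTPR2-synthetic
  segments:
  - kind: LCD2_N
    sequence: GSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQ
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
  - kind: SOLVATING_HELIX
    sequence: AEAKQNLGNAKQKQGDYQKAIEYYQ
  - kind: LCD2_C
    sequence: GSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYG
- name: LCD2-CTPR4-synthetic
  segments:
  - kind: LCD2_N
    sequence: GSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQ
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
  - kind: SOLVATING_HELIX
    sequence: AEAKQNLGNA
  - kind: LCD2_C
    sequence: GSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQ
- name: LCD2-CTPR4-FUNDC1-synthetic
  segments:
  - kind: LCD2_N
    sequence: GSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQ
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
  - kind: OTHER_LOOP
    sequence: GSGNST
  - kind: LIR_LINKER
    sequence: DPNNGSGNSTGSGNSTGSGNSDPNN
  - kind: REPEAT
    sequence: AEAWYNLGNAYYKQGDYDEAIEYYQKALEL
  - kind: LCD2_C
    sequence: GSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQGSYGQSSYG
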