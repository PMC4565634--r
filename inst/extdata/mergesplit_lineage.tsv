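T1	T2	T3	T4	T5
C1	C7	C3	C1	C3
C2	C1	C5	C7	C5
C2	C2	C5	C7	C5
C3	C4	C2	C2	C1
C3	C4	C2	C3	C1
C3	C3	C8	C6	C2
C3	C3	C1	C9	C7
C3	C3	C1	C9	C8
C4	C6	C9	C4	C6
C4	C6	C9	C10	C4
C4	C6	C9	C10	C11
C5	C8	C6	C1	C3
C6	C8	C6	C1	C3
C7	C5	C4	C5	C9
C7	C5	C7	C8	C10
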