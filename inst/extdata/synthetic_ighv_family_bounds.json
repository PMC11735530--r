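{"IGHV4-34*01":{"FR1":[1,30],"CDR1":[31,35],"FR2":[36,49],"CDR2":[50,66],"FR3":[67,98]},"IGHV1-2*01":{"FR1":[1,30],"CDR1":[31,35],"FR2":[36,49],"CDR2":[50,66],"FR3":[67,98]},"IGHV1-69*01":{"FR1":[1,30],"CDR1":[31,35],"FR2":[36,49],"CDR2":[50,66],"FR3":[67,98]},"IGHV3-23*01":{"FR1":[1,30],"CDR1":[31,35],"FR2":[36,49],"CDR2":[50,66],"FR3":[67,98]},"IGHV3-30*01":{"FR1":[1,30],"CDR1":[31,35],"FR2":[36,49],"CDR2":[50,66],"FR3":[67,98]},"IGHV4-39*01":{"FR1":[1,30],"CDR1":[31,35],"FR2":[36,49],"CDR2":[50,66],"FR3":[67,98]},"IGHV5-51*01":{"FR1":[1,30],"CDR1":[31,35],"FR2":[36,49],"CDR2":[50,66],"FR3":[67,98]}}
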