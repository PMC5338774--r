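item,subject,rating
Q1,1,5
Q1,2,5
Q1,3,6
Q2,1,5
Q2,2,6
Q2,3,6
Q3,1,4
Q3,2,6
Q3,3,6
Q4,1,4
Q4,2,6
Q4,3,6
Q5,1,5
Q5,2,5
Q5,3,5
Q6,1,3
Q6,2,4
Q6,3,6
Q7,1,3
Q7,2,6
Q7,3,6
Q8,1,3
Q8,2,6
Q8,3,6
Q9,1,4
Q9,2,5
Q9,3,6
Q10,1,4
Q10,2,5
Q10,3,6
Q11,1,6
Q11,2,6
Q11,3,6
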