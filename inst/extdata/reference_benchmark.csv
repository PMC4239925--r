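classifier,subject,tpr_mean,tpr_sd,fpr_mean,fpr_sd,gap
LS,A,75.7,4.3,18.5,10.8,4.1
LS,B,77.4,2.3,26.8,6,2.9
LS,C,67.8,6.9,29.6,7,2.3
LS,D,70.2,12.6,18.8,6.2,3.7
LS,E,72.2,3.2,31.5,7,2.3
LS,F,65.3,5.4,42.7,7.1,1.5
QP,A,78.5,2.3,17.3,11,4.5
QP,B,76.4,2.8,26.5,5.7,2.9
QP,C,69.2,6.6,31.2,7.8,2.2
QP,D,70.9,11.7,22.8,2.7,3.1
QP,E,70.8,2.6,30.4,5.1,2.3
QP,F,64.3,5.1,40.7,5,1.6
SMO,A,70.8,5,18.8,13.3,3.8
SMO,B,72.6,6.1,23.5,5.2,3.1
SMO,C,71,10.4,29.1,8.3,2.4
SMO,D,69.1,11.9,26.9,5.1,2.6
SMO,E,74.3,5.4,32.6,5.8,2.3
SMO,F,63.1,6,38.4,4.6,1.6
10-NN,A,82.6,6.4,23.1,12.8,3.6
10-NN,B,62.2,2.3,42.3,6.5,1.5
10-NN,C,57.3,7.4,52.8,10.3,1.1
10-NN,D,76.9,3.7,45.4,3.3,1.7
10-NN,E,68,3.3,42.1,5.1,1.6
10-NN,F,61.4,2,36.1,8.1,1.7
20-NN,A,85.2,3.5,21.7,12.5,3.9
20-NN,B,74.1,1.3,42.5,3.7,1.7
20-NN,C,56.8,7.2,60.2,9.5,0.9
20-NN,D,71.5,4.9,47,6.3,1.5
20-NN,E,71,4.7,43.6,3.2,1.6
20-NN,F,60.8,2.2,41.7,6.6,1.5
30-NN,A,84,3.1,21.5,10.6,3.9
30-NN,B,81.9,3.6,50.6,5.6,1.6
30-NN,C,62,5.4,54.3,11.9,1.1
30-NN,D,76.5,3,47.1,6.7,1.6
30-NN,E,72.4,3.1,43.1,5.4,1.7
30-NN,F,68.1,4.1,48.6,10.6,1.4
NB,A,73.3,2.7,19.9,10.3,3.7
NB,B,80,6.9,32.3,3.8,2.5
NB,C,59.2,11.3,41.6,5.7,1.4
NB,D,65.6,9.4,48.7,5.3,1.4
NB,E,71.5,6,40.6,10,1.8
NB,F,86.7,5.8,70.6,7.4,1.2
LS,AllUsers,71.4,5.8,28,7.4,2.8
QP,AllUsers,71.7,5.2,28.1,6.2,2.8
SMO,AllUsers,70.1,7.5,28.2,7,2.6
10-NN,AllUsers,68.1,4.2,40.3,7.7,1.9
20-NN,AllUsers,69.9,4,42.8,7,1.9
30-NN,AllUsers,74.1,3.7,44.2,8.5,1.9
NB,AllUsers,72.7,7,42.3,7.1,2
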