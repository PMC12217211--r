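1 1 0 0 0 0.5 -1
2 3 0.508271109312773 0 0 0.5 1
3 3 1.07601895312123 0.948677096597617 0 0.5 2
4 3 0.625699270278511 0.174053042017347 0 0.5 2
5 3 3.01568029072799 2.70157919522887 0 0.5 3
6 3 3.34744121959637 5.81070225606538 0 0.5 3
7 3 6.04903447893261 7.65798920213484 0 0.5 5
8 3 3.59724711730964 3.66670071286915 0 0.5 5
9 3 14.0807156771956 9.11296187168555 0 0.5 7
10 3 11.0407001907637 10.0798227286805 0 0.5 7
11 3 15.7061759947 8.89256505091437 0 0.5 9
12 3 24.9262743467277 21.1618800927862 0 0.5 9
13 3 28.9229635433894 25.6040020956509 0 0.5 12
14 3 27.5006856105618 22.6257035982045 0 0.5 12
15 3 35.8399918833367 31.6771581238467 0 0.5 13
16 3 28.9852581455052 26.7481904149076 0 0.5 13
17 3 35.7888161613133 32.678665302299 0 0.5 15
18 3 38.2343935107738 33.2022942375072 0 0.5 15
19 3 27.5770974839759 24.1411761857073 0 0.5 14
20 3 28.2930684532557 25.0918671037636 0 0.5 14
21 3 11.1113159986232 10.3671381208192 0 0.5 10
22 3 11.9646948132214 13.7041074463848 0 0.5 10
23 3 0.732849857438309 1.21095504121691 0 0.5 4
24 3 -0.295960858573659 3.26469436240685 0 0.5 4
25 3 12.9442217192774 11.2808826206434 0 0.5 21
26 3 11.4289811316627 11.1082632248409 0 0.5 21
27 3 29.1140499218433 26.8478505116129 0 0.5 16
28 3 29.1484834839079 26.8901757175998 0 0.5 16
29 3 28.5615681870341 26.4157333418441 0 0.5 20
30 3 29.1333186332642 25.3612169458655 0 0.5 20
31 3 7.21610926023101 4.69932669149391 0 0.5 8
32 3 2.43206470810586 12.0784906839036 0 0.5 8
33 3 9.11496265700672 3.9067547782529 0 0.5 31
34 3 9.62094369966762 5.30860976748885 0 0.5 31
35 3 20.8101005425629 14.089655513484 0 0.5 26
36 3 11.438130186764 11.8845096239468 0 0.5 26
37 3 38.7654672562933 33.1016271774871 0 0.5 18
38 3 42.5669964621946 35.585798321963 0 0.5 18
39 3 42.9580956517185 35.5588546703526 0 0.5 38
40 3 45.6455062245574 36.7707090182398 0 0.5 38
41 3 28.5549424074257 26.9561358106767 0 0.5 29
42 3 28.807251415386 26.5542633282735 0 0.5 29
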